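# All-women combination and multi-population aggregation.

agg_value <- function(dv, ind, yr = NULL) {
  keep <- dv$indicator == ind
  if (!is.null(yr)) keep <- keep & dv$year == yr
  unique(round(dv$value[keep], 12))
}

test_that("all-women combination is the count-weighted mean of the strata", {
  grid <- 2000:2002
  fit_in <- make_fake_fit(M = matrix(0.2, 4, 3), T = matrix(0.05, 4, 3),
                          Z = matrix(0.1, 4, 3), grid = grid, union = "Y")
  fit_not <- make_fake_fit(M = matrix(0.4, 4, 3), T = matrix(0.05, 4, 3),
                           Z = matrix(0.2, 4, 3), grid = grid, union = "N")

  # equal weights: midpoint
  counts <- make_counts(grid, n_women_y = 1e6, n_women_n = 1e6)
  dv <- combine_union_fits(fit_in, fit_not, counts, years = grid)
  expect_equal(agg_value(dv, "modern"), 0.3)

  # hand weighted mean: 3e6 x 0.40 vs 1e6 x 0.20
  fit_in2 <- make_fake_fit(M = matrix(0.40, 4, 3), T = matrix(0.05, 4, 3),
                           Z = matrix(0.1, 4, 3), grid = grid, union = "Y")
  fit_not2 <- make_fake_fit(M = matrix(0.20, 4, 3), T = matrix(0.05, 4, 3),
                            Z = matrix(0.1, 4, 3), grid = grid, union = "N")
  counts2 <- make_counts(grid, n_women_y = 3e6, n_women_n = 1e6)
  dv2 <- combine_union_fits(fit_in2, fit_not2, counts2, years = grid)
  expect_equal(agg_value(dv2, "modern"), 0.35)
  # user counts sum across strata
  expect_equal(agg_value(dv2, "users_modern"), 0.40 * 3e6 + 0.20 * 1e6)

  # degenerate weight: all women equals the in-union stratum exactly
  counts3 <- make_counts(grid, n_women_y = 2e6, n_women_n = 0)
  dv3 <- combine_union_fits(fit_in2, fit_not2, counts3, years = grid)
  expect_equal(agg_value(dv3, "modern"), 0.40)
  expect_equal(agg_value(dv3, "unmet_need"), 0.1)

  # ratio indicators are recomputed from aggregated bases
  tu <- agg_value(dv2, "total_use")
  td <- agg_value(dv2, "total_demand")
  expect_equal(agg_value(dv2, "demand_satisfied"), round(tu / td, 12))
})

test_that("population aggregation: identity, convexity, hand arithmetic", {
  grid <- 2000:2002
  counts <- make_counts(grid, divisions = c(4L, 8L))

  f1 <- make_fake_fit(M = matrix(runif(12, 0.2, 0.3), 4, 3),
                      T = matrix(0.05, 4, 3),
                      Z = matrix(runif(12, 0.1, 0.2), 4, 3),
                      grid = grid, division = 4L)
  # single fit: aggregation is the identity
  dv1 <- aggregate_populations(list(f1), counts, years = grid)
  ref <- indicator_draws(f1, counts, years = grid)
  expect_equal(dv1$value, ref$value, tolerance = 1e-12)

  # hand weighted mean: unmet {0.10, 0.20} with weights {1e6, 4e6}
  g1 <- make_fake_fit(M = matrix(0.3, 4, 3), T = matrix(0.05, 4, 3),
                      Z = matrix(0.10, 4, 3), grid = grid, division = 4L)
  g2 <- make_fake_fit(M = matrix(0.2, 4, 3), T = matrix(0.05, 4, 3),
                      Z = matrix(0.20, 4, 3), grid = grid, division = 8L)
  counts_w <- dplyr::bind_rows(
    make_counts(grid, divisions = 4L, n_women_y = 1e6),
    make_counts(grid, divisions = 8L, n_women_y = 4e6)
  )
  dvw <- aggregate_populations(list(g1, g2), counts_w, years = grid)
  expect_equal(agg_value(dvw, "unmet_need"), 0.18)

  # aggregate lies within the component range, per draw and year
  f2 <- make_fake_fit(M = matrix(runif(12, 0.4, 0.5), 4, 3),
                      T = matrix(0.05, 4, 3),
                      Z = matrix(runif(12, 0.05, 0.1), 4, 3),
                      grid = grid, division = 8L)
  dv <- aggregate_populations(list(f1, f2), counts, years = grid)
  m_agg <- dv$value[dv$indicator == "modern"]
  m1 <- indicator_draws(f1, years = grid)
  m2 <- indicator_draws(f2, years = grid)
  lo <- pmin(m1$value[m1$indicator == "modern"],
             m2$value[m2$indicator == "modern"])
  hi <- pmax(m1$value[m1$indicator == "modern"],
             m2$value[m2$indicator == "modern"])
  expect_true(all(m_agg >= lo - 1e-14 & m_agg <= hi + 1e-14))

  # users identity: aggregated count = aggregated proportion x total women
  u <- dv$value[dv$indicator == "users_modern"]
  expect_equal(u, m_agg * 2e6, tolerance = 1e-12)
})

test_that("aggregation is associative and order-invariant", {
  grid <- 2000:2002
  set.seed(5)
  mk <- function(div, w) {
    list(
      fit = make_fake_fit(M = matrix(runif(12, 0.1, 0.5), 4, 3),
                          T = matrix(runif(12, 0.02, 0.1), 4, 3),
                          Z = matrix(runif(12, 0.05, 0.2), 4, 3),
                          grid = grid, division = div),
      counts = make_counts(grid, divisions = div, n_women_y = w)
    )
  }
  a <- mk(1L, 1e6); b <- mk(2L, 2.5e6); c3 <- mk(3L, 7e5)
  counts <- dplyr::bind_rows(a$counts, b$counts, c3$counts)

  abc <- aggregate_populations(list(a$fit, b$fit, c3$fit), counts,
                               years = grid)
  perm <- aggregate_populations(list(c3$fit, a$fit, b$fit), counts,
                                years = grid)
  expect_equal(abc$value, perm$value, tolerance = 1e-12)

  # associativity: aggregate {A,B} into a pseudo-fit, then add C
  ab <- aggregate_populations(list(a$fit, b$fit), counts, years = grid)
  ab_mats <- lapply(c(modern = "modern", traditional = "traditional",
                      unmet_need = "unmet_need"), function(ind) {
    matrix(ab$value[ab$indicator == ind], nrow = 4)
  })
  ab_fit <- make_fake_fit(M = ab_mats$modern, T = ab_mats$traditional,
                          Z = ab_mats$unmet_need, grid = grid,
                          division = 99L)
  counts2 <- dplyr::bind_rows(
    make_counts(grid, divisions = 99L, n_women_y = 3.5e6), c3$counts
  )
  two_step <- aggregate_populations(list(ab_fit, c3$fit), counts2,
                                    years = grid)
  expect_equal(two_step$value[two_step$indicator == "modern"],
               abc$value[abc$indicator == "modern"], tolerance = 1e-12)
})

test_that("incompatible fits are rejected", {
  grid <- 2000:2002
  f1 <- make_fake_fit(M = matrix(0.3, 4, 3), T = matrix(0.05, 4, 3),
                      Z = matrix(0.1, 4, 3), grid = grid, division = 4L)
  f_short <- make_fake_fit(M = matrix(0.3, 2, 3), T = matrix(0.05, 2, 3),
                           Z = matrix(0.1, 2, 3), grid = grid, division = 8L)
  f_grid <- make_fake_fit(M = matrix(0.3, 4, 3), T = matrix(0.05, 4, 3),
                          Z = matrix(0.1, 4, 3), grid = 2001:2003,
                          division = 8L)
  f_dup <- make_fake_fit(M = matrix(0.2, 4, 3), T = matrix(0.05, 4, 3),
                         Z = matrix(0.1, 4, 3), grid = grid, division = 4L)
  f_union <- make_fake_fit(M = matrix(0.2, 4, 3), T = matrix(0.05, 4, 3),
                           Z = matrix(0.1, 4, 3), grid = grid, division = 8L,
                           union = "N")
  counts <- make_counts(grid, divisions = c(4L, 8L))
  expect_error(aggregate_populations(list(f1, f_short), counts), "draw counts")
  expect_error(aggregate_populations(list(f1, f_grid), counts), "grids")
  expect_error(aggregate_populations(list(f1, f_dup), counts), "duplicate")
  expect_error(aggregate_populations(list(f1, f_union), counts),
               "union status")
  expect_error(combine_union_fits(f1, f_short, counts), "draw counts")
})
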