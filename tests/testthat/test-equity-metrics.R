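test_that("the five-person worked example gives the textbook index values", {
  y <- c(0, 0, 1, 1, 1)
  f <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  # brute-force covariance oracle: E[yF] - E[y]E[F]
  cov_oracle <- mean(y * f) - mean(y) * mean(f)
  expect_equal(cov_oracle, 0.12)
  expect_equal(wagstaff_ci(y, f), 2 / 0.6 * cov_oracle)
  expect_equal(wagstaff_ci(y, f), 0.4)
  expect_equal(erreygers_ci(0.6, 0.4), 0.96)
})

test_that("degenerate and reversed rankings behave as the covariance implies", {
  f <- fractional_rank(1:6)
  expect_equal(wagstaff_ci(rep(1, 6), f), 0)           # constant outcome
  y <- c(0, 1, 0, 1, 1, 0)
  expect_equal(wagstaff_ci(y, 1 - f), -wagstaff_ci(y, f))  # antisymmetry
  expect_error(wagstaff_ci(rep(0, 6), f), "zero")
  expect_error(erreygers_ci(1.2, 0.1), "\\[0, 1\\]")
  expect_equal(erreygers_ci(0.25, 0.2), 0.2)           # 4 x 0.25 = 1
  expect_equal(erreygers_ci(0.37, 0), 0)
})

test_that("the absolute equity gap is the top-minus-bottom quintile coverage", {
  # constructed two-stratum population: bottom fifth at 0.5, top at 0.9
  y <- c(rep(c(1, 1, 0, 0), 5),               # bottom 20 children, 50%
        rep(1, 60),                           # middle: full coverage
        rep(c(1, 1, 1, 1, 1, 1, 1, 1, 1, 0), 2))  # top 20 children, 90%
  f <- fractional_rank(seq_along(y))
  res <- absolute_equity_gap(y, f)
  expect_equal(res$aeg, 0.9 - 0.5)
  expect_equal(res$quintile_summary$coverage[c(1, 5)], c(0.5, 0.9))
  expect_equal(res$quintile_summary$n, rep(20, 5))
  # uniform coverage: no gap; full coverage: no gap
  expect_equal(absolute_equity_gap(rep(c(0, 1), 10),
                                   fractional_rank(1:20))$aeg, 0)
  expect_equal(absolute_equity_gap(rep(1, 20), fractional_rank(1:20))$aeg, 0)
})

test_that("index confidence bounds follow both the literal and estimator modes", {
  y <- c(rep(0, 10), rep(1, 10))   # Var(y) = 0.25
  b <- ci_confidence_bounds(0.1, y, mode = "as_printed")
  expect_equal(b, c(0.1 - 1.96 * 0.5, 0.1 + 1.96 * 0.5))
  # Var(y) = 0.04 would give half-width 1.96 * 0.2 = 0.392
  expect_equal(1.96 * sqrt(0.04), 0.392)
  be <- ci_confidence_bounds(0.1, y, mode = "estimator")
  expect_equal(be, c(0.1 - 1.96 * sqrt(0.25 / 20), 0.1 + 1.96 * sqrt(0.25 / 20)))
  expect_equal(mean(be), 0.1)      # symmetric about the index
  expect_equal(ci_confidence_bounds(0.3, rep(1, 5)), c(0.3, 0.3))  # zero variance
  expect_error(ci_confidence_bounds(0, 1), "at least 2")
})

test_that("gap confidence bounds follow the two-quintile variance formula", {
  qs <- data.frame(quintile = c(1, 5), n = c(100, 100), n_eff = c(100, 100),
                   weight = c(100, 100), coverage = c(0.5, 0.9),
                   s2 = c(0.25, 0.09))
  b <- aeg_confidence_bounds(0.4, qs)
  expect_equal(b, 0.4 + c(-1, 1) * 1.96 * sqrt(0.09 / 100 + 0.25 / 100))
  expect_equal(round(b, 3), c(0.286, 0.514))
  qs0 <- transform(qs, s2 = 0)
  expect_equal(aeg_confidence_bounds(0.4, qs0), c(0.4, 0.4))
  expect_error(aeg_confidence_bounds(0.4, qs[qs$quintile == 5, ]),
               "quintile")
})

test_that("equity levels reproduce the published rounding of 1 - |CI|", {
  expect_equal(equity_level(0.150), 0.85)
  expect_equal(equity_level(0.054), 0.95)
  expect_equal(equity_level(0.427), 0.57)
  expect_equal(equity_level(0.425), 0.58)
  expect_equal(equity_level(0), 1.0)
  expect_equal(equity_level(-0.3), 0.7)                # sign-free
  expect_equal(equity_level(0.427, digits = NULL), 1 - 0.427)
})

test_that("concentration curves run corner to corner and integrate back to the index", {
  # constant outcome: the 45-degree diagonal
  f <- fractional_rank(1:10)
  cc <- concentration_curve(rep(1, 10), f)
  expect_equal(cc$pop_share, cc$outcome_share)
  set.seed(9)
  for (rep in 1:8) {
    n <- sample(20:150, 1)
    y <- rbinom(n, 1, 0.6)
    if (sum(y) == 0) y[1] <- 1
    w <- runif(n, 0.5, 2)
    v <- round(rnorm(n), 1)                     # ties on purpose
    f <- fractional_rank(v, w)
    cc <- concentration_curve(y, f, w)
    expect_equal(cc$pop_share[1], 0)
    expect_equal(cc$outcome_share[1], 0)
    expect_equal(cc$pop_share[nrow(cc)], 1)
    expect_equal(cc$outcome_share[nrow(cc)], 1)
    expect_true(all(diff(cc$pop_share) >= 0) && all(diff(cc$outcome_share) >= 0))
    # twice the area between curve and diagonal == covariance-form index
    expect_equal(vaxequity:::ci_from_curve(cc), wagstaff_ci(y, f, w),
                 tolerance = 1e-10)
  }
})

test_that("metrics are invariant to row order and weight scale", {
  set.seed(77)
  n <- 120
  y <- rbinom(n, 1, 0.5); v <- rnorm(n); w <- runif(n, 0.5, 4)
  f <- fractional_rank(v, w)
  ci <- wagstaff_ci(y, f, w)
  gap <- absolute_equity_gap(y, f, w)$aeg
  perm <- sample(n)
  expect_equal(wagstaff_ci(y[perm], fractional_rank(v[perm], w[perm]), w[perm]),
               ci)
  expect_equal(absolute_equity_gap(y[perm], fractional_rank(v[perm], w[perm]),
                                   w[perm])$aeg, gap)
  expect_equal(wagstaff_ci(y, fractional_rank(v, w * 13), w * 13), ci)
  expect_equal(absolute_equity_gap(y, fractional_rank(v, w * 13), w * 13)$aeg,
               gap)
})

test_that("the Erreygers identity holds to machine precision on fitted objects", {
  pop <- simulate_population(planted_residence_config(1500), seed = 6)
  for (rk in c("composite", "wealth")) {
    fit <- vaccine_equity("BCG", pop, ranking = rk, decompose = FALSE)
    expect_equal(fit$ci_erreygers, 4 * fit$mu * fit$ci_wagstaff,
                 tolerance = 1e-15)
    expect_equal(fit$equity_level, round(1 - abs(fit$ci_wagstaff), 2))
  }
})

test_that("planted pro-privileged gradients push both index and gap positive", {
  pop <- simulate_population(planted_residence_config(8000), seed = 13)
  fit <- vaccine_equity("BCG", pop, decompose = FALSE)
  expect_gt(fit$ci_wagstaff, 0)
  expect_gt(fit$aeg, 0)
  # a steeper gradient increases inequity (monotone response, same seed)
  pop2 <- simulate_population(planted_residence_config(8000, log_or = log(16)),
                              seed = 13)
  fit2 <- vaccine_equity("BCG", pop2, decompose = FALSE)
  expect_gt(fit2$ci_wagstaff, fit$ci_wagstaff)
  expect_gt(fit2$aeg, fit$aeg)
})

test_that("wealth-only and composite indices agree when SES is the only driver", {
  cfg <- sim_config(n_children = 20000,
                    effects = list(BCG = list(intercept = 0, ses = 0.8)))
  pop <- simulate_population(cfg, seed = 101)
  fc <- vaccine_equity("BCG", pop, ranking = "composite", decompose = FALSE)
  fw <- vaccine_equity("BCG", pop, ranking = "wealth", decompose = FALSE)
  expect_gt(fc$ci_wagstaff, 0)
  expect_gt(fw$ci_wagstaff, 0)
  # quintile coarsening of the continuous score leaves a small systematic gap
  expect_lt(abs(fc$ci_wagstaff - fw$ci_wagstaff), 0.02)
})
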