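test_that("fractional ranks reproduce hand-computed midpoint CDF positions", {
  expect_equal(fractional_rank(c(10, 20, 30, 40, 50)),
               c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(fractional_rank(c(1, 2), weights = c(1, 3)), c(0.125, 0.625))
  expect_equal(fractional_rank(rep(4, 7)), rep(0.5, 7))   # one tie group
  # tie group takes its weighted midpoint: values (1,2,2,3), equal weights
  expect_equal(fractional_rank(c(1, 2, 2, 3)), c(0.125, 0.5, 0.5, 0.875))
  expect_error(fractional_rank(numeric(0)), "empty")
})

test_that("fractional ranks average to one half and respect ordering", {
  set.seed(14)
  for (rep in 1:10) {
    n <- sample(5:200, 1)
    v <- sample(round(rnorm(n), sample(0:2, 1)))   # induces ties
    w <- runif(n, 0.2, 3)
    f <- fractional_rank(v, w)
    expect_equal(sum(w * f) / sum(w), 0.5, tolerance = 1e-12)
    expect_true(all(f > 0 & f < 1))
    ord <- order(v)
    expect_true(all(diff(f[ord]) >= 0))            # non-decreasing in value
  }
})

test_that("intercept-only model predicts the weighted outcome mean everywhere", {
  y <- c(0, 1, 1, 0, 1)
  w <- c(1, 2, 1, 1, 3)
  d <- data.frame(x = 1:5)
  m <- fit_direct_unfairness_model(y, d, fairness_spec(fair = character(0),
                                                       unfair = character(0),
                                                       privileged = list()),
                                   weights = w)
  expect_equal(predict_unfairness_index(m), rep(weighted.mean(y, w), 5))
})

test_that("predictions equal the row-wise inverse-logit of the linear predictor", {
  cfg <- sim_config(n_children = 600,
                    effects = list(BCG = list(intercept = -0.3,
                                              region = c(Northern = 0.8))))
  pop <- add_wealth_index(simulate_population(cfg, seed = 17))
  out <- derive_outcomes(pop, epi_schedule())
  m <- fit_direct_unfairness_model(out$BCG, pop, fairness_spec(),
                                   outcome_name = "BCG")
  X <- model.matrix(m$glm)
  manual <- 1 / (1 + exp(-as.numeric(X %*% coef(m$glm))))
  expect_equal(predict_unfairness_index(m), manual, tolerance = 1e-12)
})

test_that("planted log-odds coefficients are recovered within 3 standard errors", {
  cfg <- sim_config(n_children = 100000,
                    effects = list(BCG = list(
                      intercept = 0.2,
                      residence = c(rural = -0.9),
                      maternal_education = c(higher = 0.7))))
  pop <- add_wealth_index(simulate_population(cfg, seed = 23))
  out <- derive_outcomes(pop, epi_schedule())
  m <- fit_direct_unfairness_model(out$BCG, pop, fairness_spec(),
                                   outcome_name = "BCG")
  sm <- summary(m$glm)$coefficients
  truth <- c("residencerural" = -0.9,    # against the urban reference
             "maternal_educationhigher" = 0.7)
  for (nm in names(truth)) {
    expect_lt(abs(sm[nm, "Estimate"] - truth[[nm]]), 3 * sm[nm, "Std. Error"],
              label = paste("coefficient", nm))
  }
  expect_true(m$converged)
})

test_that("degenerate outcomes and perfect separation are refused", {
  d <- data.frame(region = rep(c("A", "B"), each = 10))
  expect_error(
    fit_direct_unfairness_model(rep(1, 20), d,
                                fairness_spec(fair = character(0),
                                              unfair = "region",
                                              privileged = list(region = "A"))),
    "degenerate outcome")
  y_sep <- rep(c(0, 1), each = 10)   # region separates the outcome perfectly
  suppressWarnings(expect_error(
    fit_direct_unfairness_model(y_sep, d,
                                fairness_spec(fair = character(0),
                                              unfair = "region",
                                              privileged = list(region = "A"))),
    "separation"))
})

test_that("unseen covariate levels in newdata are an error naming the level", {
  cfg <- sim_config(n_children = 300)
  pop <- add_wealth_index(simulate_population(cfg, seed = 2))
  out <- derive_outcomes(pop, epi_schedule())
  m <- fit_direct_unfairness_model(out$BCG, pop, fairness_spec(),
                                   outcome_name = "BCG")
  nd <- pop[1:5, ]
  nd$region[1] <- "Atlantis"
  expect_error(predict_unfairness_index(m, nd), "Atlantis")
})

test_that("privileged levels become regression reference levels", {
  spec <- fairness_spec()
  cfg <- sim_config(n_children = 400)
  pop <- add_wealth_index(simulate_population(cfg, seed = 4))
  out <- derive_outcomes(pop, epi_schedule())
  m <- fit_direct_unfairness_model(out$DPT1, pop, spec, outcome_name = "DPT1")
  expect_equal(m$reference_levels$residence, "urban")
  expect_equal(m$reference_levels$insured, "yes")
  expect_error(fairness_spec(fair = "region", unfair = c("region", "sex"),
                             privileged = list(region = "X", sex = "male")),
               "overlap")
})
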