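make_fit <- function(cfg, seed, outcome = "BCG") {
  pop <- simulate_population(cfg, seed = seed)
  vaccine_equity(outcome, pop)
}

test_that("factor shares and the residual always sum to exactly 100 percent", {
  fit <- make_fit(planted_residence_config(2500), seed = 19)
  dec <- fit$decomposition
  expect_equal(sum(dec$terms$share_percent) + dec$residual_percent, 100,
               tolerance = 1e-9)
  expect_equal(sum(dec$terms$contribution) + dec$residual, dec$ci,
               tolerance = 1e-12)
  # group shares are sums of their dummy-level shares
  for (g in dec$groups$group) {
    expect_equal(dec$groups$share_percent[dec$groups$group == g],
                 sum(dec$terms$share_percent[dec$terms$term == g]))
  }
})

test_that("a single planted unfair factor receives the dominant share", {
  fit <- make_fit(planted_residence_config(20000), seed = 29)
  g <- fit$decomposition$groups
  expect_gt(g$share_percent[g$group == "residence"], 80)
  expect_lt(abs(fit$decomposition$residual_percent), 10)
  # every other unfair factor is a bit player
  others <- g$share_percent[!g$group %in% c("residence", "age_months")]
  expect_true(all(abs(others) < 10))
})

test_that("fair-only variation leaves all unfair shares near zero", {
  # coverage driven solely by the schedule's age gating: underage children
  # cannot have received DPT3, everyone else nearly always has
  cfg <- sim_config(n_children = 20000,
                    effects = list(DPT3 = list(intercept = 2.5)))
  pop <- simulate_population(cfg, seed = 37)
  fit <- vaccine_equity("DPT3", pop)
  g <- fit$decomposition$groups
  unfair <- g$share_percent[g$group %in%
    c("region", "residence", "maternal_education", "ses_quintile",
      "sex", "insured")]
  expect_true(all(abs(unfair) < 5))
  fair_plus_resid <- sum(g$share_percent[g$group %in%
    c("age_months", "underage")]) + fit$decomposition$residual_percent
  expect_gt(fair_plus_resid, 90)
})

test_that("a zero-coefficient covariate contributes nothing", {
  pop <- simulate_population(planted_residence_config(3000), seed = 41)
  fit <- vaccine_equity("BCG", pop)
  m <- fit$model
  # force the sex coefficient to zero and recompute: its contribution vanishes
  m$glm$coefficients[grep("^sex", names(coef(m$glm)))] <- 0
  dec <- decompose_ci(m, fit$y, fit$frank, fit$weights)
  expect_equal(dec$terms$contribution[grepl("^sex", dec$terms$column)], 0,
               tolerance = 1e-12)
})

test_that("negative shares survive aggregation unclipped", {
  # a negative contribution needs covariates that pull against each other:
  # insurance helps coverage but sits mostly in the rural (low-rank) stratum,
  # so the insured dummy concentrates at the bottom of the composite ranking
  pop <- simulate_population(planted_residence_config(30000, log_or = 1.5),
                             seed = 43)
  set.seed(430)
  pop$insured <- ifelse(pop$residence == "rural",
                        sample(c("yes", "no"), nrow(pop), TRUE, c(0.85, 0.15)),
                        sample(c("yes", "no"), nrow(pop), TRUE, c(0.05, 0.95)))
  lp <- 0 + 1.5 * (pop$residence == "urban") + 0.8 * (pop$insured == "yes")
  pop$BCG <- rbinom(nrow(pop), 1, plogis(lp))
  fit <- vaccine_equity("BCG", pop)
  g <- fit$decomposition$groups
  expect_lt(g$contribution[g$group == "insured"], 0)
  expect_lt(g$share_percent[g$group == "insured"], 0)
  expect_equal(sum(g$share_percent) + fit$decomposition$residual_percent, 100,
               tolerance = 1e-9)
})

test_that("near-zero indices suppress percentage shares but keep contributions", {
  y <- rep(c(0, 1), 50)
  d <- data.frame(region = rep(c("A", "B"), each = 50))
  spec <- fairness_spec(fair = character(0), unfair = "region",
                        privileged = list(region = "A"))
  m <- fit_direct_unfairness_model(y, d, spec)
  f <- rep(0.5, 100)                    # flat ranking: CI is exactly 0
  dec <- decompose_ci(m, y, f)
  expect_true(is.na(dec$residual_percent))
  expect_true(all(is.na(dec$terms$share_percent)))
  expect_true(all(is.finite(dec$terms$contribution)))
})

test_that("custom groupings aggregate order-invariantly and must be exhaustive", {
  terms_df <- data.frame(
    column = c("regionB", "regionC", "regionD", "residencerural"),
    term = c("region", "region", "region", "residence"),
    contribution = c(0.005, 0.004, 0.0047, 0.01),
    share_percent = c(5, 4, 4.7, 10))
  g <- aggregate_factor_groups(terms_df)
  expect_equal(g$share_percent[g$group == "region"], 13.7)
  shuffled <- terms_df[c(4, 2, 1, 3), ]
  g2 <- aggregate_factor_groups(shuffled)
  expect_equal(g2[order(g2$group), ], g[order(g$group), ],
               ignore_attr = TRUE)
  custom <- c(regionB = "place", regionC = "place", residencerural = "place")
  expect_error(aggregate_factor_groups(terms_df, custom), "regionD")
  full <- c(custom, regionD = "place")
  expect_equal(aggregate_factor_groups(terms_df, full)$share_percent, 23.7)
})
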