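test_that("zero between-group variability drives batch variances to zero", {
  set.seed(41)
  groups <- rep(1:10, each = 5)
  eps <- rnorm(50, 0, 8)
  y <- eps - ave(eps, groups)          # group means exactly equal (0)
  rec <- oneway_records(y, groups)
  fit <- reml_fit(rec, terms = "composition")
  vc <- fit$varcomps
  expect_lt(vc$variance[vc$source == "composition"], 1e-8 * var(y))
  expect_equal(vc$variance[vc$source == "residual"], var(y),
               tolerance = 1e-6)
})

test_that("balanced one-way REML equals the moment-estimator oracle", {
  set.seed(42)
  a <- 8L; n <- 6L
  groups <- rep(seq_len(a), each = n)
  y <- rnorm(a, 0, 30)[groups] + rnorm(a * n, 0, 10)
  fit <- reml_fit(oneway_records(y, groups), terms = "composition")
  msb <- n * var(tapply(y, groups, mean))
  msw <- mean(tapply(y, groups, var))
  vc <- fit$varcomps
  expect_equal(vc$variance[vc$source == "composition"], (msb - msw) / n,
               tolerance = 1e-6)
  expect_equal(vc$variance[vc$source == "residual"], msw, tolerance = 1e-6)
  expect_true(fit$converged)
  # SD column is the square root of the variance column
  expect_equal(vc$sd, sqrt(vc$variance))
  expect_equal(sum(vc$percent), 100, tolerance = 1e-8)
})

test_that("REML recovers truth within 15% (median over 20 replicates)", {
  sk <- build_skeleton(default_design(), 0.192, seed = 1)
  tr <- default_truth(sk)
  truth <- c(experiment = tr$sd_experiment, block = tr$sd_block,
             composition = tr$sd_composition,
             exp_richness = tr$sd_richness_site,
             exp_composition = tr$sd_exp_composition,
             residual = tr$sd_residual)
  est <- sapply(1:20, function(rep) {
    d <- simulate_responses(sk, tr, seed = 200 + rep)
    fit <- reml_fit(d)
    vc <- fit$varcomps
    setNames(vc$sd, vc$source)[names(truth)]
  })
  med <- apply(est, 1L, median)
  for (src in names(truth))
    expect_lt(abs(med[[src]] / truth[[src]] - 1), 0.15,
              label = paste("median REML SD for", src))
})

test_that("fixed-effect F is the squared slope t-ratio", {
  d <- small_sim(seed = 17)
  fit <- reml_fit(d)
  fa <- fixed_effect_anova(fit)
  row <- fit$fixed[fit$fixed$term == "slope", ]
  expect_equal(fa$f, (row$estimate / row$se)^2, tolerance = 1e-12)
  expect_equal(fa$df, 1L)
  expect_equal(fa$ss, fa$ms)
  bad <- fit; bad$converged <- FALSE
  expect_error(fixed_effect_anova(bad), "converge")
  noslope <- reml_fit(d, terms = c("experiment", "composition"))
  expect_error(fixed_effect_anova(noslope), "slope")
})

test_that("dropping a zero-variance batch changes the deviance negligibly", {
  rec <- lrt_toy(sd_group = 0, seed = 5)
  # equalize group means exactly so the group variance is estimated at the
  # boundary by construction (block contrasts survive: blocks alternate
  # within groups, so each group mean carries the same block average)
  rec$anpp <- rec$anpp - ave(rec$anpp, rec$composition_code)
  full <- reml_fit(rec, terms = c("block", "composition"), REML = FALSE)
  vc <- full$varcomps
  expect_lt(vc$variance[vc$source == "composition"],
            1e-6 * vc$variance[vc$source == "residual"])
  out <- lrt_random_term(rec, c("block", "composition"), "composition")
  expect_lt(out$delta_deviance, 1e-4)
  expect_gte(out$delta_deviance, 0)
  expect_error(lrt_random_term(rec, c("richness", "block", "composition"),
                               "richness"), "fixed slope")
  expect_error(lrt_random_term(rec, c("block", "composition"),
                               "exp_richness"), "not in the full model")
})

test_that("boundary null gives ~50:50 zero deviances; alternative has power", {
  # scaled down from 500 to 120 replicates to stay within the test budget
  zeros <- 0L
  for (i in 1:120) {
    rec <- lrt_toy(sd_group = 0, seed = 1000 + i)
    dd <- lrt_random_term(rec, c("block", "composition"),
                          "composition")$delta_deviance
    zeros <- zeros + (dd < 1e-4)
  }
  expect_gt(zeros / 120, 0.3)
  expect_lt(zeros / 120, 0.7)

  rej <- 0L
  for (i in 1:60) {
    rec <- lrt_toy(sd_group = 30, seed = 2000 + i)   # batch SD = residual SD
    p <- lrt_random_term(rec, c("block", "composition"),
                         "composition")$p_halfmix
    rej <- rej + (p < 0.05)
  }
  expect_gt(rej / 60, 0.3)   # far above the 5% nominal level
})

test_that("BLUP slopes shrink toward the overall slope", {
  sk <- small_skeleton()
  tr <- default_truth(sk)
  wins <- 0L
  for (i in 1:20) {
    d <- simulate_responses(sk, tr, seed = 300 + i)
    fit <- reml_fit(d)
    bl <- blup_slopes(fit)
    ols <- per_site_regression(d)
    wins <- wins + (sd(bl$slope) <= sd(ols$slope, na.rm = TRUE))
  }
  expect_gte(wins, 18L)
})

test_that("zero slope-deviation variance makes all site slopes the overall", {
  sk <- small_skeleton()
  tr <- truth_params(grand_mean = 400, mean_slope = 50, sd_experiment = 0,
                     sd_block = 0, sd_richness_site = 0,
                     sd_composition = 0, sd_exp_composition = 0,
                     sd_residual = 1)
  d <- simulate_responses(sk, tr, seed = 6)
  fit <- reml_fit(d, terms = c("richness", "experiment", "exp_richness",
                               "composition"))
  bl <- blup_slopes(fit)
  overall <- fit$fixed$estimate[fit$fixed$term == "slope"]
  expect_lt(max(abs(bl$slope - overall)), 0.05)
  nofit <- reml_fit(d, terms = c("richness", "experiment", "composition"))
  expect_error(blup_slopes(nofit), "slope deviations")
})

test_that("estimates are invariant to relabeling of sites and blocks", {
  d <- small_sim(seed = 18)
  fit1 <- reml_fit(d)
  relab <- d
  relab$site <- paste0("Z", match(d$site, unique(d$site)))
  relab$block_id <- paste(relab$site, relab$block, sep = ":")
  fit2 <- reml_fit(relab)
  expect_equal(fit2$varcomps$sd, fit1$varcomps$sd, tolerance = 1e-5)
  expect_equal(fit2$fixed$estimate, fit1$fixed$estimate, tolerance = 1e-6)
})

test_that("the REML optimum is at least as good as the truth parameters", {
  d <- small_sim(seed = 19)
  tr <- attr(d, "truth")
  fit <- reml_fit(d)
  dv <- update(fit$engine, devFunOnly = TRUE)
  th_hat <- lme4::getME(fit$engine, "theta")
  sdr <- fit$varcomps$sd[fit$varcomps$source == "residual"]
  # relative-SD parameterization, matched by theta names
  th_truth <- th_hat
  key <- c("site.xc" = tr$sd_richness_site,
           "site.(Intercept)" = tr$sd_experiment,
           "block_id.(Intercept)" = tr$sd_block,
           "comp.(Intercept)" = tr$sd_composition,
           "site_comp.(Intercept)" = tr$sd_exp_composition)
  expect_true(all(names(th_hat) %in% names(key)))
  th_truth[] <- key[names(th_hat)] / tr$sd_residual
  expect_lte(dv(th_hat), dv(th_truth) + 1e-6)
})

test_that("the one-way REML profile is unimodal", {
  set.seed(44)
  groups <- rep(1:6, each = 5)
  y <- rnorm(6, 0, 12)[groups] + rnorm(30, 0, 10)
  fit <- reml_fit(oneway_records(y, groups), terms = "composition")
  dv <- update(fit$engine, devFunOnly = TRUE)
  prof <- vapply(seq(0, 4, by = 0.1), function(th) dv(th), numeric(1))
  d1 <- diff(prof)
  changes <- sum(diff(sign(d1[abs(d1) > 1e-10])) != 0)
  expect_lte(changes, 1L)
})

test_that("non-finite responses are rejected", {
  rec <- tiny_records()
  rec$anpp[2] <- Inf
  expect_error(reml_fit(rec), "non-finite")
})
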