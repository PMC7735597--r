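test_that("model weights follow the exp(-dW/2) rule and its invariances", {
  expect_equal(model_weights(42), 1)
  expect_equal(model_weights(c(10, 10)), c(0.5, 0.5))
  set.seed(41)
  for (i in 1:20) {
    W <- runif(sample(2:8, 1), 0, 40)
    w <- model_weights(W)
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
    expect_equal(w, model_weights(W + 17.3), tolerance = 1e-12)
  }
  expect_error(model_weights(numeric(0)), "empty")
  expect_error(model_weights(c(1, Inf)), "finite")
})

test_that("WAIC has zero penalty for a degenerate posterior and matches the formula", {
  ds <- paperlike_dataset()
  f1 <- fake_fit(ds, n = 40, jitter = 0.01)
  # identical draws: variance penalty must vanish
  f0 <- f1
  f0$draws <- f1$draws[rep(1, 10), , drop = FALSE]
  f0$chain <- rep(1L, 10)
  w0 <- compute_waic(f0, ds$inputs)
  expect_equal(w0$p_waic, 0, tolerance = 1e-12)
  expect_equal(w0$waic, -2 * w0$lppd, tolerance = 1e-10)
  # hand evaluation of the WAIC formula from the pointwise matrix
  w1 <- compute_waic(f1, ds$inputs)
  ll <- w1$pointwise
  expect_equal(ncol(ll), nrow(ds$obs$cpue) + 5L)
  lppd_hand <- sum(log(colMeans(exp(ll))))
  p_hand <- sum(apply(ll, 2, var))
  expect_equal(w1$lppd, lppd_hand, tolerance = 1e-8)
  expect_equal(w1$p_waic, p_hand, tolerance = 1e-8)
  expect_equal(w1$waic, -2 * (lppd_hand - p_hand), tolerance = 1e-8)
  # each pointwise row sums to the draw's total log likelihood
  par <- f1$draws[1, ]
  tr <- project_population(par, ds$truth$spec, ds$inputs)
  tot <- loglik_cpue(tr, ds$obs, par[["k"]], par[["sigma_obs"]]) +
    loglik_trend(tr, ds$obs) +
    loglik_window_logits(tr, "adult", ds$obs) +
    loglik_window_logits(tr, "fecundity", ds$obs) +
    loglik_window_logits(tr, "juvenile", ds$obs, r_j = par[["r_j"]]) +
    loglik_chicks_2005(tr, ds$obs)
  expect_equal(sum(ll[1, ]), tot, tolerance = 1e-10)
  # the CPUE-only partition drops the five constraint columns
  wc <- compute_waic(f1, ds$inputs, points = "cpue")
  expect_equal(ncol(wc$pointwise), nrow(ds$obs$cpue))
})

test_that("the selection table recomputes weights and breaks ties by name", {
  W <- c(M_b = 100, M_a = 100, M_c = 103)
  tab <- waic_table(as.list(W))
  expect_equal(tab$model, c("M_a", "M_b", "M_c"))
  expect_equal(tab$delta_w, c(0, 0, 3))
  expect_equal(sum(tab$weight), 1, tolerance = 1e-12)
})

test_that("lag-grid expansion proposes models only beyond an occupied boundary", {
  specs <- default_model_set()
  # interior best model within the survival grid -2..1: no proposal
  tab <- data.frame(model = c("S-1F0", "S0F0"), W = c(1, 2))
  expect_length(expand_lag_grid(tab, specs), 0)
  # best at the survival boundary -2 proposes -3
  tab2 <- data.frame(model = c("S-2F0", "S-1F0"), W = c(1, 2))
  out <- expand_lag_grid(tab2, specs)
  expect_equal(names(out), "S-3F0")
  # a constant-survival best model never extends the survival axis, but a
  # fecundity boundary still does
  tab3 <- data.frame(model = c("NoSF0", "S0F0"), W = c(1, 2))
  out3 <- expand_lag_grid(tab3, specs[c("NoSF0", "S0F0")])
  expect_setequal(names(out3), c("NoSF-1", "NoSF1"))
})

test_that("model averaging pools by largest remainder and guards lag-specific slopes", {
  ds <- paperlike_dataset()
  fA <- fake_fit(ds, n = 60, seed = 1)
  fB <- fake_fit(ds, n = 60, seed = 2)
  fB$spec <- model_spec(0L, 0L)
  fits <- list("S-1F0" = fA, "S0F0" = fB)
  avg <- model_average(fits, c(0.7, 0.3), size = 10, seed = 5)
  expect_equal(sum(avg$pick$model == "S-1F0"), 7)
  expect_equal(sum(avg$pick$model == "S0F0"), 3)
  # degenerate weights draw everything from one model
  avg1 <- model_average(fits, c(1, 0), size = 20, seed = 5)
  expect_true(all(avg1$pick$model == "S-1F0"))
  # beta_s is lag-specific here; beta_f shares lag 0... but survival lags
  # differ so only beta_s is refused
  expect_error(averaged_parameter(avg, "beta_s"), "model-specific")
  expect_silent(averaged_parameter(avg, "beta_f"))
  # pooled mean of a shared scalar approximates the weighted mean
  big <- model_average(fits, c(0.7, 0.3), size = 4000, seed = 6)
  pooled <- mean(averaged_parameter(big, "r"))
  target <- 0.7 * mean(fA$draws[, "r"]) + 0.3 * mean(fB$draws[, "r"])
  expect_equal(pooled, target, tolerance = 0.02)
})

test_that("MCMC is seed-deterministic and honours the model structure", {
  ds <- paperlike_dataset()
  st <- tiny_settings(n_iter = 800, n_burn = 400, thin = 4)
  f1 <- fit(ds$truth$spec, ds$inputs, st, seed = 7)
  f2 <- fit(ds$truth$spec, ds$inputs, st, seed = 7)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$lp, f2$lp)
  expect_equal(nrow(f1$draws), 2 * (800 - 400) / 4)
  # the degenerate NoSNoF model has no slope columns
  f3 <- fit(model_spec(NA, NA), ds$inputs, st, seed = 7)
  expect_false(any(c("beta_s", "beta_f") %in% colnames(f3$draws)))
  expect_true(all(c("alpha_s", "alpha_f", "r", "k") %in% colnames(f3$draws)))
  # prior-rejection initialisation also finds a finite start
  f4 <- fit(ds$truth$spec, ds$inputs,
            tiny_settings(n_iter = 300, n_burn = 200, thin = 2),
            seed = 8, init = "prior")
  expect_true(all(is.finite(f4$lp)))
})

test_that("short-chain posterior concentrates near the generating truth", {
  ds <- paperlike_dataset()
  st <- tiny_settings(n_iter = 6000, n_burn = 3000, thin = 6)
  f <- fit(ds$truth$spec, ds$inputs, st, seed = 3)
  for (nm in c("beta_f", "k", "N1a", "alpha_f")) {
    z <- abs(mean(f$draws[, nm]) - ds$truth$params[[nm]]) /
      sd(f$draws[, nm])
    expect_lt(z, 4)
  }
})

test_that("posterior predictive intervals behave like the observation model", {
  ds <- paperlike_dataset()
  # truth-only draws: intervals must match the normal quantiles around
  # k * n0 analytically
  f <- fake_fit(ds, n = 400, jitter = 0)
  pp <- posterior_predictive_cpue(f, ds$inputs, seed = 2)
  tr <- project_population(ds$truth$params, ds$truth$spec, ds$inputs)
  k <- ds$truth$params[["k"]]; s <- ds$truth$params[["sigma_obs"]]
  mu <- k * tr$n[1, pp$t]
  expect_equal(pp$pred_mean, mu, tolerance = 0.02)
  expect_equal(pp$hi - pp$lo, rep(2 * qnorm(0.975) * s, nrow(pp)),
               tolerance = 0.15)
  # near-zero observation noise collapses the interval onto k * n0
  f2 <- fake_fit(ds, n = 200, jitter = 0)
  f2$draws[, "sigma_obs"] <- 1e-8
  pp2 <- posterior_predictive_cpue(f2, ds$inputs, seed = 2)
  expect_equal(pp2$lo, mu, tolerance = 1e-6)
  expect_equal(pp2$hi, mu, tolerance = 1e-6)
  # on data generated from the model, observed values sit inside the
  # intervals (the qualitative adequacy check)
  expect_gte(mean(pp$inside), 0.9)
})
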