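make_traj <- function(ds) {
  project_population(ds$truth$params, ds$truth$spec, ds$inputs)
}

test_that("observation data enforces the CPUE year whitelist", {
  ok <- observation_data(data.frame(year = c(1979, 1992, 1994, 1998),
                                    cpue = 1:4))
  expect_s3_class(ok, "titi_obs")
  expect_equal(ok$cpue$t, c(4, 17, 19, 23))
  expect_error(observation_data(data.frame(year = 1993, cpue = 1)), "1993")
  expect_error(observation_data(data.frame(year = 1978, cpue = 1)), "1978")
  expect_error(observation_data(data.frame(year = 1999, cpue = 1)), "1999")
  expect_error(
    observation_data(data.frame(year = c(1980, 1980), cpue = 1:2)),
    "duplicate")
})

test_that("CPUE likelihood matches the closed-form normal density", {
  ds <- paperlike_dataset()
  tr <- make_traj(ds)
  k <- ds$truth$params[["k"]]
  # a single observation exactly at its mean
  obs1 <- observation_data(data.frame(year = 1980,
                                      cpue = k * tr$n[1, 5]))
  expect_equal(loglik_cpue(tr, obs1, k, 2), -log(2 * sqrt(2 * pi)))
  # empty CPUE set contributes nothing
  obs0 <- observation_data(data.frame(year = integer(0),
                                      cpue = numeric(0)))
  expect_equal(loglik_cpue(tr, obs0, k, 2), 0)
  # three synthetic points against a hand-written density formula
  yrs <- c(1981, 1985, 1996)
  vals <- c(10, 25, 31)
  obs3 <- observation_data(data.frame(year = yrs, cpue = vals))
  mu <- k * tr$n[1, yrs - 1975]
  byhand <- sum(-0.5 * log(2 * pi * 4) - (vals - mu)^2 / 8)
  expect_equal(loglik_cpue(tr, obs3, k, 2), byhand)
  expect_error(loglik_cpue(tr, obs3, k, 0), "sigma_obs")
})

test_that("trend likelihood uses the 29-interval geometric rate", {
  ds <- paperlike_dataset()
  tr <- make_traj(ds)
  obs <- ds$obs
  # constant adult series gives lambda_m = 1
  tr1 <- tr; tr1$N_a <- rep(5e6, 30)
  expect_equal(loglik_trend(tr1, obs),
               dnorm(obs$lambda_hat, 1, 0.002, log = TRUE))
  # a series built to decline at exactly lambda_hat maximises the term
  tr2 <- tr; tr2$N_a <- 5e6 * obs$lambda_hat^(0:29)
  expect_equal(loglik_trend(tr2, obs), dnorm(0, 0, 0.002, log = TRUE))
  # exp-log oracle on the fitted trajectory
  lam <- exp(log(tr$N_a[30] / tr$N_a[1]) / 29)
  expect_equal(loglik_trend(tr, obs),
               dnorm(obs$lambda_hat, lam, 0.002, log = TRUE))
  tr3 <- tr; tr3$N_a[1] <- 0
  expect_error(loglik_trend(tr3, obs), "adults")
})

test_that("window constraints average generalized logits over the printed windows", {
  ds <- paperlike_dataset()
  tr <- make_traj(ds)
  obs <- ds$obs
  cst <- fixed_constants()
  # constant adult survival 0.952 under ceiling 0.98
  tr1 <- tr; tr1$s_a <- rep(0.952, 29)
  expect_equal(
    loglik_window_logits(tr1, "adult", obs, cst),
    dnorm(obs$l_hat_a, log(0.952 / 0.028), obs$sigma_a, log = TRUE))
  # the printed juvenile logit is the logit of the printed survival rate
  expect_equal(log(0.566 / 0.434), 0.266, tolerance = 3e-3)
  # r_j = 1 centres the juvenile constraint on the window mean itself
  lbar_j <- mean(qlogis(tr$s_j[21:28]))
  expect_equal(
    loglik_window_logits(tr, "juvenile", obs, cst, r_j = 1),
    dnorm(obs$l_hat_j, lbar_j, obs$sigma_j, log = TRUE))
  # fecundity window is 1997-99 plus 2003-05
  lbar_f <- mean(log(tr$f[c(22:24, 28:30)] /
                       (0.9 - tr$f[c(22:24, 28:30)])))
  expect_equal(loglik_window_logits(tr, "fecundity", obs, cst),
               dnorm(obs$l_hat_f, lbar_f, obs$sigma_f_obs, log = TRUE))
  # a rate at its ceiling makes the logit undefined
  tr2 <- tr; tr2$s_a[25] <- 0.98
  expect_error(loglik_window_logits(tr2, "adult", obs, cst), "maximum")
})

test_that("2005 chick constraint works in millions and is always finite", {
  ds <- paperlike_dataset()
  tr <- make_traj(ds)
  obs <- ds$obs
  tr1 <- tr; tr1$n[1, 30] <- obs$n_hat_chicks * 1e6
  expect_equal(loglik_chicks_2005(tr1, obs),
               -log(obs$sigma_n * sqrt(2 * pi)))
  tr2 <- tr; tr2$n[1, 30] <- 0
  v <- loglik_chicks_2005(tr2, obs)
  expect_true(is.finite(v) && v < -100)
  # maximised when the trajectory hits the estimate
  grid <- seq(1e6, 5e6, length.out = 41)
  vals <- vapply(grid, function(g) {
    trg <- tr; trg$n[1, 30] <- g; loglik_chicks_2005(trg, obs)
  }, numeric(1))
  expect_equal(grid[which.max(vals)],
               grid[which.min(abs(grid - obs$n_hat_chicks * 1e6))])
})

test_that("log prior matches a term-by-term oracle and encodes supports", {
  pr <- prior_config()
  spec <- model_spec(-1L, 0L)
  par <- demographic_parameters(alpha_s = 3, beta_s = 0.5, alpha_f = 0.2,
                                beta_f = 0.3, r = 0.6, r_j = 0.9, k = 1e-5,
                                sigma_obs = 2, N1a = 20, mu_p = 7.2,
                                sigma_p = 1.7)
  lp <- log_prior(par, spec, pr)
  d <- c(7.2, 1.7) - c(7.5, 1.9)
  S <- diag(c(0.5^2, 0.25^2))
  byhand <- dnorm(3, 0, 100, log = TRUE) + dnorm(0.5, 0, 100, log = TRUE) +
    dnorm(0.2, 0, 100, log = TRUE) + dnorm(0.3, 0, 100, log = TRUE) +
    log(1 / 1000) + log(1 / 1000) + log(1 / 100) +
    (-log(2 * pi) - 0.5 * log(det(S)) -
       0.5 * drop(t(d) %*% solve(S) %*% d))
  expect_equal(lp, byhand, tolerance = 1e-12)
  # support violations return -Inf
  bad <- par; bad[["r"]] <- 1.5
  expect_identical(log_prior(bad, spec, pr), -Inf)
  bad2 <- par; bad2[["N1a"]] <- 101
  expect_identical(log_prior(bad2, spec, pr), -Inf)
  bad3 <- par; bad3[["sigma_p"]] <- -1
  expect_identical(log_prior(bad3, spec, pr), -Inf)
  # constant-survival models carry no beta_s prior term
  lp_nos <- log_prior(par, model_spec(NA, 0L), pr)
  expect_equal(lp_nos, byhand - dnorm(0.5, 0, 100, log = TRUE))
})

test_that("log posterior is the sum of its parts and propagates -Inf", {
  ds <- paperlike_dataset()
  spec <- ds$truth$spec
  inp <- ds$inputs
  cst <- inp$constants
  set.seed(31)
  for (i in 1:20) {
    par <- ds$truth$params * exp(rnorm(11, 0, 0.02))
    tr <- project_population(par, spec, inp)
    parts <- log_prior(par, spec, inp$prior) +
      loglik_cpue(tr, inp$obs, par[["k"]], par[["sigma_obs"]]) +
      loglik_trend(tr, inp$obs) +
      loglik_window_logits(tr, "adult", inp$obs, cst) +
      loglik_window_logits(tr, "fecundity", inp$obs, cst) +
      loglik_window_logits(tr, "juvenile", inp$obs, cst, par[["r_j"]]) +
      loglik_chicks_2005(tr, inp$obs)
    expect_equal(as.numeric(log_posterior(par, spec, inp)), parts,
                 tolerance = 1e-12)
  }
  bad <- ds$truth$params; bad[["r"]] <- -0.2
  lp <- log_posterior(bad, spec, inp)
  expect_identical(as.numeric(lp), -Inf)
  expect_match(attr(lp, "reason"), "support")
  # a projection failure (harvest above chicks) also maps to -Inf
  tiny <- ds$truth$params; tiny[["N1a"]] <- 0.001
  lp2 <- log_posterior(tiny, spec, inp)
  expect_identical(as.numeric(lp2), -Inf)
})
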