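#' Observation data for the assessment
#'
#' Holds the scaled CPUE index and the five auxiliary summary constraints
#' with their standard errors. Usable CPUE exists only for the Rama
#' (surface-catching) period of 1979--1992 and 1994--1998; 1993 and years
#' outside that span are rejected. The default constraint values are the
#' published regional estimates: burrow-density trend `lambda_hat` with SE
#' `sigma_lambda`; window-averaged generalized logits of adult survival,
#' fecundity and juvenile survival (`l_hat_a`, `l_hat_f`, `l_hat_j`); and
#' the 2005 chick abundance in millions (`n_hat_chicks`).
#'
#' @param cpue Data frame with columns `year` (calendar) and `cpue`.
#' @param lambda_hat,sigma_lambda Adult-abundance trend estimate and SE.
#' @param l_hat_a,sigma_a Adult-survival logit estimate (window 1996--2004)
#'   and SE, on the `log(s / (s_max - s))` scale.
#' @param l_hat_f,sigma_f_obs Fecundity logit estimate (windows 1997--99
#'   and 2003--05) and SE, on the `log(f / (f_max - f))` scale.
#' @param l_hat_j,sigma_j Juvenile-survival logit estimate (window
#'   1996--2003) and SE, on the ordinary logit scale.
#' @param n_hat_chicks,sigma_n 2005 chick abundance estimate and SE
#'   (millions).
#' @return Object of class `titi_obs`.
#' @export
observation_data <- function(cpue,
                             lambda_hat = 0.983, sigma_lambda = 0.002,
                             l_hat_a = 2.987, sigma_a = 0.422,
                             l_hat_f = 0.08, sigma_f_obs = 0.108,
                             l_hat_j = 0.266, sigma_j = 0.155,
                             n_hat_chicks = 2.787, sigma_n = 0.132) {
  stopifnot(is.data.frame(cpue), all(c("year", "cpue") %in% names(cpue)),
            sigma_lambda > 0, sigma_a > 0, sigma_f_obs > 0, sigma_j > 0,
            sigma_n > 0)
  bad <- setdiff(cpue$year, CPUE_YEARS)
  if (length(bad) > 0)
    stop(sprintf(
      "CPUE supplied for ineligible year(s) %s: usable CPUE is restricted to 1979-1992 and 1994-1998",
      paste(sort(bad), collapse = ", ")))
  if (anyDuplicated(cpue$year)) stop("duplicate CPUE years")
  cpue <- cpue[order(cpue$year), c("year", "cpue")]
  cpue$t <- calendar_to_model_year(cpue$year)
  structure(
    list(cpue = cpue,
         lambda_hat = lambda_hat, sigma_lambda = sigma_lambda,
         l_hat_a = l_hat_a, sigma_a = sigma_a,
         l_hat_f = l_hat_f, sigma_f_obs = sigma_f_obs,
         l_hat_j = l_hat_j, sigma_j = sigma_j,
         n_hat_chicks = n_hat_chicks, sigma_n = sigma_n),
    class = "titi_obs")
}

#' CPUE log likelihood
#'
#' Each observed CPUE value is normal around `k` times the chick abundance
#' of its year, with residual SD `sigma_obs`; `k` plays the role of a
#' catchability coefficient.
#'
#' @param traj A `titi_trajectory`.
#' @param obs An [observation_data()] object.
#' @param k Catchability (CPUE units per chick).
#' @param sigma_obs Residual SD (CPUE units).
#' @return Scalar log likelihood (0 for an empty CPUE set).
#' @export
loglik_cpue <- function(traj, obs, k, sigma_obs) {
  if (sigma_obs <= 0) stop("sigma_obs must be > 0")
  if (nrow(obs$cpue) == 0) return(0)
  if (any(obs$cpue$t < 1 | obs$cpue$t > length(traj$N)))
    stop("CPUE year outside the trajectory")
  sum(stats::dnorm(obs$cpue$cpue, k * traj$n[1, obs$cpue$t], sigma_obs,
                   log = TRUE))
}

#' Adult-trend log likelihood
#'
#' The modelled trend is the geometric annual growth of adult abundance,
#' `(N_a[30] / N_a[1])^(1/29)`; the burrow-density trend estimate is normal
#' around it.
#'
#' @inheritParams loglik_cpue
#' @return Scalar log likelihood.
#' @export
loglik_trend <- function(traj, obs) {
  nT <- length(traj$N_a)
  if (traj$N_a[1] <= 0) stop("no adults in year 1")
  lambda_m <- (traj$N_a[nT] / traj$N_a[1])^(1 / (nT - 1))
  stats::dnorm(obs$lambda_hat, lambda_m, obs$sigma_lambda, log = TRUE)
}

# generalized logit of a rate against its ceiling
glogit <- function(x, x_max) log(x / (x_max - x))

#' Window-averaged vital-rate constraints
#'
#' Averages the generalized logit of the modelled rate over the window the
#' corresponding field estimate covers, then evaluates the normal density
#' of the estimate at that mean. Adult survival uses
#' `log(s / (s_max - s))` over 1996--2004; fecundity `log(f / (f_max - f))`
#' over 1997--99 and 2003--05; juvenile survival the ordinary logit over
#' 1996--2003, with its constraint centred at `r_j` times the window mean
#' (the mark-recapture estimate is a lower bound because emigrants are
#' counted as deaths, and `r_j` in `[0, 1]` absorbs that bias).
#'
#' @inheritParams loglik_cpue
#' @param which One of `"adult"`, `"fecundity"`, `"juvenile"`.
#' @param constants A [fixed_constants()] object.
#' @param r_j Juvenile-constraint scaling (used only for `"juvenile"`).
#' @return Scalar log likelihood.
#' @export
loglik_window_logits <- function(traj, which, obs,
                                 constants = fixed_constants(), r_j = 1) {
  which <- match.arg(which, c("adult", "fecundity", "juvenile"))
  if (which == "adult") {
    s <- traj$s_a[WINDOW_ADULT]
    if (any(s >= constants$s_max_a) || any(s <= 0))
      stop("adult survival at or beyond its maximum; logit undefined")
    lbar <- mean(glogit(s, constants$s_max_a))
    stats::dnorm(obs$l_hat_a, lbar, obs$sigma_a, log = TRUE)
  } else if (which == "fecundity") {
    f <- traj$f[WINDOW_FECUND]
    if (any(f >= constants$f_max) || any(f <= 0))
      stop("fecundity at or beyond its maximum; logit undefined")
    lbar <- mean(glogit(f, constants$f_max))
    stats::dnorm(obs$l_hat_f, lbar, obs$sigma_f_obs, log = TRUE)
  } else {
    sj <- traj$s_j[WINDOW_JUVENILE]
    if (any(sj >= 1) || any(sj <= 0))
      stop("juvenile survival outside (0, 1); logit undefined")
    lbar <- mean(stats::qlogis(sj))
    stats::dnorm(obs$l_hat_j, r_j * lbar, obs$sigma_j, log = TRUE)
  }
}

#' 2005 chick-abundance log likelihood
#'
#' The independent estimate of chick numbers in the final model year
#' (millions) is normal around the modelled `n[0, 30]`.
#'
#' @inheritParams loglik_cpue
#' @return Scalar log likelihood.
#' @export
loglik_chicks_2005 <- function(traj, obs) {
  nT <- length(traj$N)
  stats::dnorm(obs$n_hat_chicks, traj$n[1, nT] / 1e6, obs$sigma_n,
               log = TRUE)
}

#' Prior configuration
#'
#' Vague normal priors with SD 100 on the link intercepts and slopes,
#' uniforms on `[0, 1000]` for `k` and `sigma_obs`, on `[0, 1]` for `r` and
#' `r_j`, and on `[0, 100]` (millions) for `N1a`. Age at maturity
#' `(mu_p, sigma_p)` has a bivariate normal prior centred at (7.5, 1.9);
#' the published covariance matrix of that estimate is not available, so
#' the default is diagonal with SDs (0.5, 0.25) -- a weakly informative
#' stand-in, configurable here.
#'
#' @param coef_sd SD of the normal prior on link intercepts/slopes.
#' @param k_max,sigma_max,N1a_max Upper bounds of the uniform supports.
#' @param maturity_mean,maturity_cov Bivariate normal prior on
#'   `(mu_p, sigma_p)`.
#' @return Named list.
#' @export
prior_config <- function(coef_sd = 100, k_max = 1000, sigma_max = 1000,
                         N1a_max = 100, maturity_mean = c(7.5, 1.9),
                         maturity_cov = diag(c(0.5^2, 0.25^2))) {
  list(coef_sd = coef_sd, k_max = k_max, sigma_max = sigma_max,
       N1a_max = N1a_max, maturity_mean = maturity_mean,
       maturity_cov = maturity_cov,
       maturity_prec = solve(maturity_cov),
       maturity_ldet = determinant(maturity_cov, logarithm = TRUE)$modulus[1])
}

# bivariate normal log density given precomputed precision/log-determinant
ldmvnorm2 <- function(x, mean, prec, ldet) {
  d <- x - mean
  -log(2 * pi) - 0.5 * ldet - 0.5 * sum(d * (prec %*% d))
}

#' Joint log prior
#'
#' Sum of the prior log densities of [prior_config()]; returns `-Inf`
#' outside any support.
#'
#' @param par A [demographic_parameters()] vector (or plain named vector).
#' @param spec A [model_spec()]; determines which slopes exist.
#' @param prior A [prior_config()] list.
#' @return Scalar log prior density.
#' @export
log_prior <- function(par, spec = model_spec(), prior = prior_config()) {
  r <- par[["r"]]; r_j <- par[["r_j"]]; k <- par[["k"]]
  so <- par[["sigma_obs"]]; N1a <- par[["N1a"]]; sp <- par[["sigma_p"]]
  if (r < 0 || r > 1 || r_j < 0 || r_j > 1 ||
      k < 0 || k > prior$k_max || so <= 0 || so > prior$sigma_max ||
      N1a < 0 || N1a > prior$N1a_max || sp <= 0)
    return(-Inf)
  lp <- -log(prior$k_max) - log(prior$sigma_max) - log(prior$N1a_max)
  lp <- lp + stats::dnorm(par[["alpha_s"]], 0, prior$coef_sd, log = TRUE) +
    stats::dnorm(par[["alpha_f"]], 0, prior$coef_sd, log = TRUE)
  if (!is.na(spec$lag_s))
    lp <- lp + stats::dnorm(par[["beta_s"]], 0, prior$coef_sd, log = TRUE)
  if (!is.na(spec$lag_f))
    lp <- lp + stats::dnorm(par[["beta_f"]], 0, prior$coef_sd, log = TRUE)
  lp + ldmvnorm2(c(par[["mu_p"]], sp), prior$maturity_mean,
                 prior$maturity_prec, prior$maturity_ldet)
}

# Pointwise log-likelihood contributions for one trajectory: one entry per
# CPUE observation plus the five auxiliary constraints. Used by the
# posterior and by WAIC.
pointwise_core <- function(res, inputs, k, sigma_obs, r_j) {
  obs <- inputs$obs
  cst <- inputs$constants
  nT <- cst$n_years
  ll_cpue <- stats::dnorm(obs$cpue$cpue, k * res$n[1, obs$cpue$t],
                          sigma_obs, log = TRUE)
  lambda_m <- (res$N_a[nT] / res$N_a[1])^(1 / (nT - 1))
  ll_tr <- stats::dnorm(obs$lambda_hat, lambda_m, obs$sigma_lambda,
                        log = TRUE)
  sa <- res$rates$s_a[WINDOW_ADULT]
  ll_a <- stats::dnorm(obs$l_hat_a, mean(glogit(sa, cst$s_max_a)),
                       obs$sigma_a, log = TRUE)
  fw <- res$rates$f[WINDOW_FECUND]
  ll_f <- stats::dnorm(obs$l_hat_f, mean(glogit(fw, cst$f_max)),
                       obs$sigma_f_obs, log = TRUE)
  sj <- res$rates$s_j[WINDOW_JUVENILE]
  ll_j <- stats::dnorm(obs$l_hat_j, r_j * mean(stats::qlogis(sj)),
                       obs$sigma_j, log = TRUE)
  ll_n <- stats::dnorm(obs$n_hat_chicks, res$n[1, nT] / 1e6, obs$sigma_n,
                       log = TRUE)
  c(ll_cpue, trend = ll_tr, adult = ll_a, fecundity = ll_f,
    juvenile = ll_j, chicks = ll_n)
}

#' Joint log posterior
#'
#' Log prior plus all likelihood terms, evaluated on the trajectory the
#' parameter vector implies (run-in plus projection). Support violations
#' and projection failures (harvest exceeding chicks, bycatch exceeding the
#' population) yield `-Inf`, with the reason attached as attribute
#' `"reason"`.
#'
#' @param par Named parameter vector; when the model carries process error,
#'   entries `eps_s1..eps_s29` and `eps_f1..eps_f30` are the logit-scale
#'   disturbances.
#' @param spec A [model_spec()].
#' @param inputs An [assessment_inputs()] bundle.
#' @return Scalar log posterior density (up to a constant).
#' @export
log_posterior <- function(par, spec, inputs) {
  lp <- log_prior(par, spec, inputs$prior)
  if (!is.finite(lp)) return(structure(-Inf, reason = "outside prior support"))
  eps_s <- eps_f <- NULL
  if (spec$sigma_s_proc > 0) {
    eps_s <- par[paste0("eps_s", 1:29)]
    lp <- lp + sum(stats::dnorm(eps_s, 0, spec$sigma_s_proc, log = TRUE))
  }
  if (spec$sigma_f_proc > 0) {
    eps_f <- par[paste0("eps_f", 1:30)]
    lp <- lp + sum(stats::dnorm(eps_f, 0, spec$sigma_f_proc, log = TRUE))
  }
  drivers <- apply_lags(inputs$covariates, spec)
  res <- trajectory_core(par, drivers, inputs, eps_s, eps_f)
  if (!res$ok) return(structure(-Inf, reason = res$reason))
  pll <- pointwise_core(res, inputs, par[["k"]], par[["sigma_obs"]],
                        par[["r_j"]])
  out <- lp + sum(pll)
  if (!is.finite(out)) return(structure(-Inf, reason = "non-finite likelihood"))
  out
}
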