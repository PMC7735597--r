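#' Climate-lag model specification
#'
#' A model is identified by the lag applied to each climate link. Lag 0
#' means survival (or fecundity) in year `t` is driven by the covariate of
#' year `t`; lag -1 means the covariate of year `t` drives the rate in year
#' `t - 1`; lag +1 drives the rate in year `t + 1`. `NA` on an axis means
#' that rate is constant over time ("NoS" / "NoF"). Optional process-error
#' standard deviations add year-specific logit-scale disturbances to the
#' links; they are fixed inputs, never estimated.
#'
#' @param lag_s Survival lag (integer) or `NA` for constant survival.
#' @param lag_f Fecundity lag (integer) or `NA` for constant fecundity.
#' @param sigma_s_proc,sigma_f_proc Process-error SDs (logit scale, >= 0).
#' @return An object of class `titi_model_spec` with a canonical `name`
#'   such as `"S-1F0"`, `"NoSF0"` or `"NoSNoF"`.
#' @export
model_spec <- function(lag_s = 0L, lag_f = 0L,
                       sigma_s_proc = 0, sigma_f_proc = 0) {
  lag_s <- if (is.null(lag_s) || is.na(lag_s)) NA_integer_ else as.integer(lag_s)
  lag_f <- if (is.null(lag_f) || is.na(lag_f)) NA_integer_ else as.integer(lag_f)
  stopifnot(sigma_s_proc >= 0, sigma_f_proc >= 0)
  name <- paste0(
    if (is.na(lag_s)) "NoS" else paste0("S", lag_s),
    if (is.na(lag_f)) "NoF" else paste0("F", lag_f))
  structure(list(lag_s = lag_s, lag_f = lag_f, name = name,
                 sigma_s_proc = sigma_s_proc, sigma_f_proc = sigma_f_proc),
            class = "titi_model_spec")
}

#' @export
print.titi_model_spec <- function(x, ...) {
  cat(sprintf("model %s (lag_s=%s, lag_f=%s, sigma_proc=%g/%g)\n", x$name,
              ifelse(is.na(x$lag_s), "none", x$lag_s),
              ifelse(is.na(x$lag_f), "none", x$lag_f),
              x$sigma_s_proc, x$sigma_f_proc))
  invisible(x)
}

#' The candidate model set for climate-lag selection
#'
#' All combinations of lags -1, 0, +1 on both survival and fecundity (nine
#' models), the boundary expansion S-2F0, and the three reduced models
#' NoSF0, S-1NoF and NoSNoF -- thirteen models in all.
#'
#' @return Named list of [model_spec()] objects.
#' @export
default_model_set <- function() {
  specs <- list()
  for (ls in c(-1L, 0L, 1L)) for (lf in c(-1L, 0L, 1L))
    specs[[length(specs) + 1L]] <- model_spec(ls, lf)
  specs[[length(specs) + 1L]] <- model_spec(-2L, 0L)
  specs[[length(specs) + 1L]] <- model_spec(NA, 0L)
  specs[[length(specs) + 1L]] <- model_spec(-1L, NA)
  specs[[length(specs) + 1L]] <- model_spec(NA, NA)
  names(specs) <- vapply(specs, `[[`, character(1), "name")
  specs
}

#' Demographic parameter vector
#'
#' Assembles and validates the estimated parameters of the model. Abundance
#' `N1a` is in millions of adults; everything else is dimensionless or in
#' CPUE units (`k`, `sigma_obs`).
#'
#' @param alpha_s,beta_s Logit-scale intercept and slope of the adult
#'   survival link (`beta_s` may be `NA` for constant-survival models).
#' @param alpha_f,beta_f Intercept and slope of the fecundity link.
#' @param r Juvenile-to-adult survival ratio, in `[0, 1]`.
#' @param r_j Scaling of the juvenile survival constraint, in `[0, 1]`.
#' @param k CPUE catchability (CPUE units per chick), > 0.
#' @param sigma_obs CPUE residual SD (CPUE units), > 0.
#' @param N1a Adults in model year 1 (millions), in `[0, 100]`.
#' @param mu_p,sigma_p Mean and SD of age at maturity (years).
#' @return Named numeric vector of class `titi_params`.
#' @export
demographic_parameters <- function(alpha_s, beta_s = NA_real_,
                                   alpha_f, beta_f = NA_real_,
                                   r, r_j, k, sigma_obs, N1a,
                                   mu_p = 7.5, sigma_p = 1.9) {
  stopifnot(r >= 0, r <= 1, r_j >= 0, r_j <= 1, k > 0, sigma_obs > 0,
            N1a >= 0, N1a <= 100, sigma_p > 0)
  out <- c(alpha_s = alpha_s, beta_s = beta_s, alpha_f = alpha_f,
           beta_f = beta_f, r = r, r_j = r_j, k = k, sigma_obs = sigma_obs,
           N1a = N1a, mu_p = mu_p, sigma_p = sigma_p)
  class(out) <- "titi_params"
  out
}

#' Annual forcing series: harvest and bycatch counts
#'
#' @param H Chick harvest counts for model years 1--29 (individuals).
#' @param B Bycatch totals for model years 1--29 (individuals). Bycatch is
#'   taken as negligible from the 2002 season onward, so the final three
#'   entries must be zero.
#' @return Object of class `titi_forcing`.
#' @export
forcing_series <- function(H, B) {
  stopifnot(length(H) == 29L, length(B) == 29L)
  if (any(H < 0) || any(B < 0)) stop("forcing counts must be >= 0")
  late <- which(model_year_to_calendar(1:29) >= 2002L)
  if (any(B[late] != 0))
    stop("bycatch must be zero for calendar years 2002 onward")
  structure(list(H = as.numeric(H), B = as.numeric(B)),
            class = "titi_forcing")
}

#' Initializer rates for the Leslie stable-age seed
#'
#' Central demographic values used only to form the initializer Leslie
#' matrix whose stable-age distribution seeds the five-year run-in. The
#' run-in washes out this choice; the defaults are representative central
#' rates (juvenile survival near the geometric mean of first- and
#' second-year survival in the congeneric short-tailed shearwater), and all
#' values are configurable.
#'
#' @param s_a,s_j,f Initializer survival and fecundity rates.
#' @param mu_p,sigma_p Initializer maturity-curve parameters.
#' @return Named list.
#' @export
leslie_initializer <- function(s_a = 0.95, s_j = 0.665, f = 0.52,
                               mu_p = 7.5, sigma_p = 1.9) {
  list(s_a = s_a, s_j = s_j, f = f, mu_p = mu_p, sigma_p = sigma_p)
}

#' Bundle everything a posterior evaluation needs
#'
#' Packs covariates, forcing, observations and constants together, and
#' precomputes the fixed stable-age seed vector of the initializer Leslie
#' matrix (the initializer uses fixed central rates, so the seed vector is
#' parameter-independent and computed once per bundle).
#'
#' @param covariates A [annual_covariates()] object.
#' @param forcing A [forcing_series()] object.
#' @param obs An [observation_data()] object.
#' @param constants A [fixed_constants()] object.
#' @param init A [leslie_initializer()] list.
#' @param prior A [prior_config()] list.
#' @return Object of class `titi_inputs`.
#' @export
assessment_inputs <- function(covariates, forcing, obs,
                              constants = fixed_constants(),
                              init = leslie_initializer(),
                              prior = prior_config()) {
  stopifnot(inherits(covariates, "titi_covariates"),
            inherits(forcing, "titi_forcing"),
            inherits(obs, "titi_obs"),
            inherits(constants, "titi_constants"))
  p0 <- maturity_probabilities(init$mu_p, init$sigma_p)
  M <- build_leslie_matrix(init$s_a, init$s_j, init$f, p0, constants)
  sad <- stable_age_distribution(M)
  structure(
    list(covariates = covariates, forcing = forcing, obs = obs,
         constants = constants, init = init, prior = prior,
         stable_age = sad$vector, stable_lambda = sad$lambda),
    class = "titi_inputs")
}

# Annual vital-rate series implied by a parameter vector and lag drivers.
# eps_s / eps_f are optional logit-scale process errors (lengths 29, 30).
vital_rate_series <- function(par, drivers, constants,
                              eps_s = NULL, eps_f = NULL) {
  xs <- par[["alpha_s"]]
  if (!is.null(drivers$zs_drive)) xs <- xs + par[["beta_s"]] * drivers$zs_drive
  xs <- rep_len(xs, 30L)
  if (!is.null(eps_s)) xs[1:29] <- xs[1:29] + eps_s
  xf <- par[["alpha_f"]]
  if (!is.null(drivers$zf_drive)) xf <- xf + par[["beta_f"]] * drivers$zf_drive
  xf <- rep_len(xf, 30L)
  if (!is.null(eps_f)) xf <- xf + eps_f
  s_a <- constants$s_max_a * stats::plogis(xs)
  f <- constants$f_max * stats::plogis(xf)
  list(s_a = s_a[1:29], s_j = par[["r"]] * s_a[1:29], f = f)
}

# Full pipeline from parameters to a trajectory; returns ok=FALSE with a
# reason instead of throwing (posterior hot path).
trajectory_core <- function(par, drivers, inputs, eps_s = NULL, eps_f = NULL) {
  cst <- inputs$constants
  rates <- vital_rate_series(par, drivers, cst, eps_s, eps_f)
  p <- maturity_probabilities(par[["mu_p"]], par[["sigma_p"]])
  N1a_ind <- par[["N1a"]] * 1e6
  u <- inputs$stable_age
  scale0 <- N1a_ind / sum(p * u)
  if (!is.finite(scale0) || scale0 <= 0)
    return(list(ok = FALSE, reason = "non-positive initial scale"))
  h1 <- inputs$forcing$H[1] / (scale0 * u[1])
  b1 <- inputs$forcing$B[1] / scale0  # u sums to 1
  if (h1 >= 1) return(list(ok = FALSE, reason = "run-in harvest rate >= 1"))
  if (b1 >= 1) return(list(ok = FALSE, reason = "run-in bycatch rate >= 1"))
  v <- u
  for (kk in seq_len(cst$run_in_years))
    v <- step_core(v, rates$s_a[1], rates$s_j[1], rates$f[1], b1,
                   h1 * v[1], p, cst$w)
  adults <- sum(p * v)
  if (!is.finite(adults) || adults <= 0)
    return(list(ok = FALSE, reason = "run-in lost all adults"))
  n1 <- v * (N1a_ind / adults)
  if (!all(is.finite(n1)))
    return(list(ok = FALSE, reason = "non-finite run-in abundance"))
  res <- project_core(n1, rates$s_a, rates$s_j, rates$f,
                      inputs$forcing$H, inputs$forcing$B, p, cst$w,
                      cst$n_years)
  if (!res$ok) return(res)
  res$rates <- rates
  res$p <- p
  res
}

#' Project the population for a given parameter vector
#'
#' Runs the full deterministic pipeline -- climate links, run-in, 30-year
#' projection with the forcing series -- for one parameter vector.
#'
#' @param par A [demographic_parameters()] vector.
#' @param spec A [model_spec()].
#' @param inputs An [assessment_inputs()] bundle.
#' @param eps_s,eps_f Optional logit-scale process errors (lengths 29, 30).
#' @return A `titi_trajectory` (see [project()]).
#' @export
project_population <- function(par, spec, inputs, eps_s = NULL, eps_f = NULL) {
  drivers <- apply_lags(inputs$covariates, spec)
  res <- trajectory_core(par, drivers, inputs, eps_s, eps_f)
  if (!res$ok) stop(res$reason)
  structure(
    list(n = res$n, N = res$N, N_a = res$N_a,
         s_a = res$rates$s_a, s_j = res$rates$s_j, f = res$rates$f,
         b = res$b, h = res$h,
         years = model_year_to_calendar(seq_len(inputs$constants$n_years))),
    class = "titi_trajectory")
}
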