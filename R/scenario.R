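SCENARIO_LABELS <- c("baseline", "no_harvest", "no_bycatch", "no_weka",
                     "no_climate_survival", "no_climate_fecundity",
                     "no_all_managed")

#' Counterfactual "virtual population" projection
#'
#' Re-projects every posterior draw with one mortality mechanism removed,
#' leaving all other sampled parameters untouched: `no_harvest` sets the
#' harvest series to zero, `no_bycatch` zeroes bycatch, `no_weka` sets the
#' depredation probability `w` to zero, `no_climate_survival` /
#' `no_climate_fecundity` set the corresponding link slope to zero (the
#' rate becomes the draw's intercept-only value; juvenile survival, being
#' `r * s_a`, is flattened along with adult survival), and
#' `no_all_managed` removes harvest, bycatch and weka together.
#'
#' @param fitobj A [fit()] result or [model_average()] object.
#' @param scenario One of `"baseline"`, `"no_harvest"`, `"no_bycatch"`,
#'   `"no_weka"`, `"no_climate_survival"`, `"no_climate_fecundity"`,
#'   `"no_all_managed"`.
#' @param inputs The matching [assessment_inputs()] bundle.
#' @param growth_on `"total"` (matches the published framing) or
#'   `"adult"`.
#' @return Object of class `titi_counterfactual`: per-draw total-abundance
#'   matrix `N` (draws x years), per-draw annual decline percentages
#'   `growth_pct`, and a `summary` row (mean and central 95% interval of
#'   the decline).
#' @export
run_counterfactual <- function(fitobj, scenario, inputs,
                               growth_on = c("total", "adult")) {
  growth_on <- match.arg(growth_on)
  if (!scenario %in% SCENARIO_LABELS)
    stop(sprintf("unknown scenario '%s'", scenario))
  inp <- inputs
  if (scenario %in% c("no_harvest", "no_all_managed"))
    inp$forcing$H <- rep(0, length(inp$forcing$H))
  if (scenario %in% c("no_bycatch", "no_all_managed"))
    inp$forcing$B <- rep(0, length(inp$forcing$B))
  if (scenario %in% c("no_weka", "no_all_managed"))
    inp$constants$w <- 0
  kill_bs <- scenario == "no_climate_survival"
  kill_bf <- scenario == "no_climate_fecundity"
  driv_cache <- new.env()
  get_drivers <- function(spec) {
    if (is.null(driv_cache[[spec$name]]))
      driv_cache[[spec$name]] <- apply_lags(inp$covariates, spec)
    driv_cache[[spec$name]]
  }
  rows <- each_draw(fitobj, function(par, spec, eps_s, eps_f) {
    if (kill_bs && "beta_s" %in% names(par)) par[["beta_s"]] <- 0
    if (kill_bf && "beta_f" %in% names(par)) par[["beta_f"]] <- 0
    res <- trajectory_core(par, get_drivers(spec), inp, eps_s, eps_f)
    if (!res$ok) stop("counterfactual projection failed: ", res$reason)
    c(res$N, res$N_a)
  })
  nT <- inputs$constants$n_years
  M <- do.call(rbind, rows)
  N <- M[, seq_len(nT), drop = FALSE]
  N_a <- M[, nT + seq_len(nT), drop = FALSE]
  G <- if (growth_on == "total") N else N_a
  growth_pct <- 100 * (1 - (G[, nT] / G[, 1])^(1 / (nT - 1)))
  structure(
    list(scenario = scenario, N = N, N_a = N_a, growth_pct = growth_pct,
         summary = data.frame(
           scenario = scenario,
           decline_pct_mean = mean(growth_pct),
           decline_pct_lo = unname(stats::quantile(growth_pct, 0.025)),
           decline_pct_hi = unname(stats::quantile(growth_pct, 0.975)))),
    class = "titi_counterfactual")
}

#' Annualised growth (reported as percent decline per year)
#'
#' `100 * (1 - (N_end / N_start)^(1 / (T - 1)))`: positive values are
#' declines, negative values growth. The default uses total abundance,
#' matching the usual framing of whole-population change; `"adult"`
#' annualises the adult series instead.
#'
#' @param traj A `titi_trajectory`, or a numeric abundance series.
#' @param which `"total"` or `"adult"` (ignored for a numeric series).
#' @return Percent decline per year (scalar).
#' @export
annual_growth <- function(traj, which = c("total", "adult")) {
  which <- match.arg(which)
  N <- if (is.numeric(traj)) traj
       else if (which == "total") traj$N else traj$N_a
  if (N[1] <= 0) stop("initial population must be > 0")
  100 * (1 - (N[length(N)] / N[1])^(1 / (length(N) - 1)))
}

#' Process-error SD from a coverage requirement
#'
#' For a logistic link with coefficients `alpha`, `beta`, the SD `sigma`
#' that makes the rate reach `rate_bound` at the extreme covariate value
#' with a two-SD disturbance solves
#' `rate_max / (1 + exp(-(alpha + beta z -/+ 2 sigma))) = rate_bound`,
#' giving the closed form
#' `sigma = +/-(alpha + beta z - log(rate_bound / (rate_max - rate_bound))) / 2`
#' -- minus-shift at the lower bound (`side = "lower"`, evaluated at the
#' minimum observed covariate), plus-shift at the upper bound
#' (`side = "upper"`, at the maximum). The configured process SD is the
#' maximum of the two sides.
#'
#' @param alpha,beta Link coefficients (e.g. posterior means).
#' @param z_extreme The extreme observed covariate value for that side.
#' @param rate_bound Required extreme rate, strictly inside
#'   `(0, rate_max)`.
#' @param rate_max The link ceiling.
#' @param side `"lower"` or `"upper"`.
#' @return Non-negative `sigma`; errors if the bound is already violated
#'   without noise (negative solution).
#' @export
solve_process_sigma <- function(alpha, beta, z_extreme, rate_bound,
                                rate_max, side = c("lower", "upper")) {
  side <- match.arg(side)
  if (rate_bound <= 0 || rate_bound >= rate_max)
    stop("rate_bound must be strictly inside (0, rate_max)")
  target <- log(rate_bound / (rate_max - rate_bound))
  eta <- alpha + beta * z_extreme
  sigma <- if (side == "lower") (eta - target) / 2 else (target - eta) / 2
  if (sigma < 0)
    stop("bound already violated without noise (negative sigma)")
  sigma
}

#' Process-error configuration from a fitted model
#'
#' Recomputes the "high" process-error SDs from the posterior means of the
#' link coefficients: the survival SD makes true adult survival span
#' `survival_range` over the observed covariate extremes, the fecundity SD
#' makes fecundity span `fecundity_range`; each SD is the maximum of its
#' lower- and upper-side solutions.
#'
#' @param fitobj A fitted `titi_fit` for the model being modified.
#' @param inputs The matching [assessment_inputs()] bundle.
#' @param survival_range Range the true adult survival must cover
#'   (default `c(0.65, 0.97)`).
#' @param fecundity_range Range the true fecundity must cover
#'   (default `c(0.2, 0.8)`).
#' @return List with `sigma_s`, `sigma_f` and the per-side solutions.
#' @export
process_error_config <- function(fitobj, inputs,
                                 survival_range = c(0.65, 0.97),
                                 fecundity_range = c(0.2, 0.8)) {
  cst <- inputs$constants
  drivers <- apply_lags(inputs$covariates, fitobj$spec)
  if (is.null(drivers$zs_drive) || is.null(drivers$zf_drive))
    stop("process-error calibration needs climate links on both rates")
  zs <- range(drivers$zs_drive[1:29])
  zf <- range(drivers$zf_drive)
  a_s <- mean(fitobj$draws[, "alpha_s"]); b_s <- mean(fitobj$draws[, "beta_s"])
  a_f <- mean(fitobj$draws[, "alpha_f"]); b_f <- mean(fitobj$draws[, "beta_f"])
  # a side whose bound is already exceeded without noise needs no
  # disturbance on that side: it contributes zero to the pairwise maximum
  side0 <- function(alpha, beta, z, bound, rmax, side) {
    tryCatch(solve_process_sigma(alpha, beta, z, bound, rmax, side),
             error = function(e) 0)
  }
  s_lo <- side0(a_s, b_s, zs[1], survival_range[1], cst$s_max_a, "lower")
  s_hi <- side0(a_s, b_s, zs[2], survival_range[2], cst$s_max_a, "upper")
  f_lo <- side0(a_f, b_f, zf[1], fecundity_range[1], cst$f_max, "lower")
  f_hi <- side0(a_f, b_f, zf[2], fecundity_range[2], cst$f_max, "upper")
  if (max(s_lo, s_hi) == 0 || max(f_lo, f_hi) == 0)
    stop("both coverage bounds already violated without noise; no positive process SD exists")
  list(sigma_s = max(s_lo, s_hi), sigma_f = max(f_lo, f_hi),
       sides = c(s_lower = s_lo, s_upper = s_hi,
                 f_lower = f_lo, f_upper = f_hi))
}

#' Input-perturbation sensitivity variants
#'
#' The standard set of single-substitution alternatives to the best model:
#' bycatch series scaled up or down (`B-HIGH1`, `B-HIGH2` additionally
#' holds the post-1990 series at its 1990 level, `B-LOW`), the fecundity
#' estimate at 0.8x / 1.2x (`F-LOW` 0.416, `F-HIGH` 0.624), maximum
#' fecundity 0.8 (`FM-LOW`), maximum survival 0.999 (`SM-HIGH`), harvest
#' series scaled down/up (`H-LOW`, `H-HIGH`), and the trend estimate one
#' percentage point below/above (`T-LOW` 0.973, `T-HIGH` 0.993). The
#' published upper/lower bycatch and harvest limits are not reproducible
#' from the text, so the series multipliers are configurable arguments.
#'
#' @param bycatch_high,bycatch_low,harvest_low,harvest_high Multipliers
#'   applied to the corresponding forcing series.
#' @return Named list of variant descriptors
#'   (`name`, `target`, `field`, `value`).
#' @export
sensitivity_variants <- function(bycatch_high = 2, bycatch_low = 0.5,
                                 harvest_low = 0.75, harvest_high = 1.25) {
  v <- list(
    list(name = "B-HIGH1", target = "forcing_B_mult", value = bycatch_high),
    list(name = "B-HIGH2", target = "forcing_B_mult_hold1990",
         value = bycatch_high),
    list(name = "B-LOW", target = "forcing_B_mult", value = bycatch_low),
    list(name = "F-LOW", target = "obs", field = "l_hat_f",
         value = glogit(0.416, 0.9)),
    list(name = "F-HIGH", target = "obs", field = "l_hat_f",
         value = glogit(0.624, 0.9)),
    list(name = "FM-LOW", target = "constants", field = "f_max", value = 0.8),
    list(name = "SM-HIGH", target = "constants", field = "s_max_a",
         value = 0.999),
    list(name = "H-LOW", target = "forcing_H_mult", value = harvest_low),
    list(name = "H-HIGH", target = "forcing_H_mult", value = harvest_high),
    list(name = "T-LOW", target = "obs", field = "lambda_hat", value = 0.973),
    list(name = "T-HIGH", target = "obs", field = "lambda_hat", value = 0.993))
  names(v) <- vapply(v, `[[`, character(1), "name")
  v
}

# apply one sensitivity substitution to an inputs bundle
apply_variant <- function(inputs, variant) {
  inp <- inputs
  if (variant$target == "obs") {
    inp$obs[[variant$field]] <- variant$value
  } else if (variant$target == "constants") {
    inp$constants[[variant$field]] <- variant$value
  } else if (variant$target == "forcing_H_mult") {
    inp$forcing$H <- inp$forcing$H * variant$value
  } else if (variant$target == "forcing_B_mult") {
    inp$forcing$B <- inp$forcing$B * variant$value
  } else if (variant$target == "forcing_B_mult_hold1990") {
    B <- inp$forcing$B * variant$value
    t1990 <- calendar_to_model_year(1990L)
    B[seq_along(B) > t1990] <- B[t1990]
    inp$forcing$B <- B
  } else stop(sprintf("unknown variant target '%s'", variant$target))
  inp
}

#' Run the input-perturbation sensitivity suite
#'
#' Refits the model once per variant with the single substitution applied
#' and reports the link-slope posteriors plus the 2005 relative-population
#' ratios `N_30(baseline) / N_30(scenario)` for the no-harvest,
#' no-bycatch, no-weka and all-three-removed counterfactuals.
#'
#' @param variants List from [sensitivity_variants()] (any subset).
#' @param spec The best-model [model_spec()].
#' @param inputs Baseline [assessment_inputs()].
#' @param settings [mcmc_settings()] used for every refit.
#' @param seed Integer seed (offset per variant).
#' @param include_baseline Prepend an unmodified fit labelled `baseline`.
#' @return Data frame `variant, quantity, mean, lo95, hi95`.
#' @export
run_sensitivity_suite <- function(variants, spec, inputs,
                                  settings = mcmc_settings(), seed = 1L,
                                  include_baseline = TRUE) {
  jobs <- variants
  if (include_baseline)
    jobs <- c(list(baseline = list(name = "baseline", target = "none")), jobs)
  out <- list()
  for (i in seq_along(jobs)) {
    v <- jobs[[i]]
    inp <- if (identical(v$target, "none")) inputs else
      apply_variant(inputs, v)
    f <- fit(spec, inp, settings, seed + i)
    base_N30 <- run_counterfactual(f, "baseline", inp)$N[, inputs$constants$n_years]
    q <- function(x) c(mean = mean(x),
                       lo95 = unname(stats::quantile(x, 0.025)),
                       hi95 = unname(stats::quantile(x, 0.975)))
    rows <- list()
    for (b in intersect(c("beta_s", "beta_f"), colnames(f$draws)))
      rows[[b]] <- q(f$draws[, b])
    for (sc in c("no_harvest", "no_bycatch", "no_weka", "no_all_managed")) {
      cf <- run_counterfactual(f, sc, inp)
      rows[[paste0("ratio_", sc)]] <-
        q(base_N30 / cf$N[, inputs$constants$n_years])
    }
    out[[v$name]] <- do.call(rbind, lapply(names(rows), function(nm)
      data.frame(variant = v$name, quantity = nm,
                 mean = rows[[nm]][["mean"]], lo95 = rows[[nm]][["lo95"]],
                 hi95 = rows[[nm]][["hi95"]])))
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
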