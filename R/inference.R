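#' MCMC settings
#'
#' Defaults mirror the full assessment runs: two chains of 200,000
#' iterations, the first half discarded as burn-in, thinned 1-in-20 so each
#' chain retains 5,000 draws. Tests and examples scale these down.
#'
#' @param n_iter Iterations per chain.
#' @param n_burn Burn-in iterations discarded (adaptation happens here).
#' @param thin Thinning interval for retained draws.
#' @param n_chains Number of chains.
#' @param target_accept Target acceptance rate of the adaptive proposal.
#' @param rhat_warn,rhat_error Convergence-diagnostic thresholds: warn when
#'   any potential scale reduction factor exceeds `rhat_warn`, error beyond
#'   `rhat_error` (set to `Inf` to disable).
#' @param eps_block Sub-block size for the latent process-error updates
#'   (small blocks keep acceptance workable at large process SDs; with
#'   near-zero SDs a single full block is cheapest).
#' @return Named list of class `titi_mcmc_settings`.
#' @export
mcmc_settings <- function(n_iter = 200000L, n_burn = 100000L, thin = 20L,
                          n_chains = 2L, target_accept = 0.234,
                          rhat_warn = 1.05, rhat_error = 1.2,
                          eps_block = 8L) {
  stopifnot(n_iter > n_burn, thin >= 1, n_chains >= 1, eps_block >= 1)
  structure(list(n_iter = as.integer(n_iter), n_burn = as.integer(n_burn),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 target_accept = target_accept, rhat_warn = rhat_warn,
                 rhat_error = rhat_error, eps_block = as.integer(eps_block)),
            class = "titi_mcmc_settings")
}

# ---- parameter transforms (natural <-> unbounded sampling scale) --------

free_param_names <- function(spec) {
  nm <- c("alpha_s",
          if (!is.na(spec$lag_s)) "beta_s",
          "alpha_f",
          if (!is.na(spec$lag_f)) "beta_f",
          "r", "r_j", "k", "sigma_obs", "N1a", "mu_p", "sigma_p")
  if (spec$sigma_s_proc > 0) nm <- c(nm, paste0("eps_s", 1:29))
  if (spec$sigma_f_proc > 0) nm <- c(nm, paste0("eps_f", 1:30))
  nm
}

# transform type per parameter: identity, logit on (0, upper), or log
transform_table <- function(names, prior) {
  upper <- rep(NA_real_, length(names))
  type <- rep("identity", length(names))
  type[names %in% c("r", "r_j")] <- "logit"
  upper[names %in% c("r", "r_j")] <- 1
  type[names == "k"] <- "logit"; upper[names == "k"] <- prior$k_max
  type[names == "sigma_obs"] <- "logit"
  upper[names == "sigma_obs"] <- prior$sigma_max
  type[names == "N1a"] <- "logit"; upper[names == "N1a"] <- prior$N1a_max
  type[names == "sigma_p"] <- "log"
  list(names = names, type = type, upper = upper)
}

to_unbounded <- function(par, tt) {
  x <- par[tt$names]
  i <- tt$type == "logit"
  x[i] <- stats::qlogis(pmin(pmax(par[tt$names[i]] / tt$upper[i], 1e-12),
                             1 - 1e-12))
  j <- tt$type == "log"
  x[j] <- log(par[tt$names[j]])
  x
}

to_natural <- function(x, tt) {
  par <- x
  i <- tt$type == "logit"
  par[i] <- tt$upper[i] * stats::plogis(x[i])
  j <- tt$type == "log"
  par[j] <- exp(x[j])
  names(par) <- tt$names
  par
}

log_jacobian <- function(x, tt) {
  out <- 0
  i <- tt$type == "logit"
  if (any(i)) {
    p <- stats::plogis(x[i])
    out <- out + sum(log(tt$upper[i]) + log(p) + log1p(-p))
  }
  j <- tt$type == "log"
  if (any(j)) out <- out + sum(x[j])
  out
}

# posterior on the sampling scale, with drivers precomputed
make_lp_x <- function(spec, inputs, tt) {
  drivers <- apply_lags(inputs$covariates, spec)
  has_es <- spec$sigma_s_proc > 0
  has_ef <- spec$sigma_f_proc > 0
  ies <- if (has_es) match(paste0("eps_s", 1:29), tt$names) else NULL
  ief <- if (has_ef) match(paste0("eps_f", 1:30), tt$names) else NULL
  function(x) {
    par <- to_natural(x, tt)
    lp <- log_prior(par, spec, inputs$prior)
    if (!is.finite(lp)) return(-Inf)
    eps_s <- if (has_es) unname(par[ies]) else NULL
    eps_f <- if (has_ef) unname(par[ief]) else NULL
    if (has_es)
      lp <- lp + sum(stats::dnorm(eps_s, 0, spec$sigma_s_proc, log = TRUE))
    if (has_ef)
      lp <- lp + sum(stats::dnorm(eps_f, 0, spec$sigma_f_proc, log = TRUE))
    res <- trajectory_core(par, drivers, inputs, eps_s, eps_f)
    if (!res$ok) return(-Inf)
    ll <- sum(pointwise_core(res, inputs, par[["k"]], par[["sigma_obs"]],
                             par[["r_j"]]))
    val <- lp + ll + log_jacobian(x, tt)
    if (!is.finite(val)) -Inf else val
  }
}

# data-informed starting point on the natural scale
heuristic_start <- function(spec, inputs) {
  obs <- inputs$obs
  n_hat_ind <- obs$n_hat_chicks * 1e6
  N1a0 <- min(max(n_hat_ind / (0.5 * (1 - inputs$constants$w) * 0.5) *
                    1.5 / 1e6, 1), 95)
  cp <- obs$cpue$cpue
  k0 <- if (length(cp) > 0) mean(cp) / (n_hat_ind * 1.3) else 1e-5
  s0 <- if (length(cp) > 1) max(stats::sd(cp) * 0.5, 1e-3) else 1
  par <- c(alpha_s = 3, beta_s = 0.3, alpha_f = 0, beta_f = 0.3,
           r = 0.6, r_j = 0.8, k = k0, sigma_obs = s0, N1a = N1a0,
           mu_p = 7.5, sigma_p = 1.9)
  par <- par[c("alpha_s",
               if (!is.na(spec$lag_s)) "beta_s",
               "alpha_f",
               if (!is.na(spec$lag_f)) "beta_f",
               "r", "r_j", "k", "sigma_obs", "N1a", "mu_p", "sigma_p")]
  if (spec$sigma_s_proc > 0) {
    e <- rep(0, 29); names(e) <- paste0("eps_s", 1:29); par <- c(par, e)
  }
  if (spec$sigma_f_proc > 0) {
    e <- rep(0, 30); names(e) <- paste0("eps_f", 1:30); par <- c(par, e)
  }
  par
}

# draw one parameter vector from the priors (for rejection initialisation)
prior_draw <- function(spec, inputs) {
  pr <- inputs$prior
  mat <- pr$maturity_mean + drop(chol(pr$maturity_cov) %*% stats::rnorm(2))
  par <- c(alpha_s = stats::rnorm(1, 0, pr$coef_sd),
           beta_s = stats::rnorm(1, 0, pr$coef_sd),
           alpha_f = stats::rnorm(1, 0, pr$coef_sd),
           beta_f = stats::rnorm(1, 0, pr$coef_sd),
           r = stats::runif(1), r_j = stats::runif(1),
           k = stats::runif(1, 0, pr$k_max),
           sigma_obs = stats::runif(1, 0, pr$sigma_max),
           N1a = stats::runif(1, 0, pr$N1a_max),
           mu_p = mat[1], sigma_p = abs(mat[2]))
  par[free_param_names(spec)[!grepl("^eps_", free_param_names(spec))]]
}

# Gelman-Rubin potential scale reduction factor per column
rhat_diag <- function(draws, chain) {
  chains <- split(seq_len(nrow(draws)), chain)
  if (length(chains) < 2) return(rep(NA_real_, ncol(draws)))
  n <- min(lengths(chains))
  vapply(seq_len(ncol(draws)), function(j) {
    xs <- lapply(chains, function(i) draws[i[seq_len(n)], j])
    means <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, stats::var, numeric(1))
    W <- mean(vars)
    B <- n * stats::var(means)
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
}

#' Fit a climate-lag model by adaptive Metropolis MCMC
#'
#' Samples the joint posterior with a random-walk Metropolis whose proposal
#' covariance is adapted (empirical covariance scaled by `2.38^2 / d`, with
#' a global scale tuned to the target acceptance rate) during burn-in and
#' frozen afterwards. Sampling happens on an unbounded transformed scale
#' (logit for the bounded parameters, log for `sigma_p`), with the Jacobian
#' included.
#'
#' @param spec A [model_spec()].
#' @param inputs An [assessment_inputs()] bundle.
#' @param settings A [mcmc_settings()] list.
#' @param seed Integer seed; chains use deterministic offsets of it.
#' @param init `"auto"` (heuristic start polished by a short optimisation;
#'   the default), `"prior"` (rejection sampling from the priors until the
#'   posterior is finite), or a named numeric vector used directly.
#' @return Object of class `titi_fit`: `draws` (retained draws, natural
#'   scale), `chain`, `lp`, `rhat`, `accept`, plus the spec, settings and
#'   seed.
#' @export
fit <- function(spec, inputs, settings = mcmc_settings(), seed = 1L,
                init = "auto") {
  tt <- transform_table(free_param_names(spec), inputs$prior)
  lp_x <- make_lp_x(spec, inputs, tt)
  d <- length(tt$names)

  set.seed(seed)
  if (is.numeric(init)) {
    x0 <- to_unbounded(init[tt$names], tt)
    if (!is.finite(lp_x(x0))) stop("supplied init has non-finite posterior")
  } else if (identical(init, "prior")) {
    x0 <- NULL
    for (i in 1:1000) {
      cand <- heuristic_start(spec, inputs)
      pd <- prior_draw(spec, inputs)
      cand[names(pd)] <- pd
      xc <- to_unbounded(cand, tt)
      if (is.finite(lp_x(xc))) { x0 <- xc; break }
    }
    if (is.null(x0))
      stop("no finite starting point found by prior sampling")
  } else {
    cand <- heuristic_start(spec, inputs)
    x0 <- NULL
    for (mult in c(1, 1.5, 2, 3, 5, 0.7, 0.5)) {
      c2 <- cand
      c2[["N1a"]] <- min(cand[["N1a"]] * mult, inputs$prior$N1a_max * 0.99)
      xc <- to_unbounded(c2, tt)
      if (is.finite(lp_x(xc))) { x0 <- xc; break }
    }
    if (is.null(x0)) stop("heuristic start has non-finite posterior")
    main <- !grepl("^eps_", tt$names)
    obj <- function(z) {
      xx <- x0; xx[main] <- z
      v <- lp_x(xx)
      if (!is.finite(v)) 1e10 else -v
    }
    opt <- stats::optim(x0[main], obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-10))
    x0[main] <- opt$par
  }

  n_keep <- (settings$n_iter - settings$n_burn) %/% settings$thin
  draws <- matrix(NA_real_, n_keep * settings$n_chains, d,
                  dimnames = list(NULL, tt$names))
  lp_keep <- numeric(n_keep * settings$n_chains)
  chain_id <- integer(n_keep * settings$n_chains)
  accept <- numeric(settings$n_chains)

  is_eps <- grepl("^eps_", tt$names)
  main <- which(!is_eps)
  eps_i <- which(is_eps)
  d_m <- length(main)
  eps_sd <- c(rep(spec$sigma_s_proc, sum(grepl("^eps_s", tt$names))),
              rep(spec$sigma_f_proc, sum(grepl("^eps_f", tt$names))))

  for (ch in seq_len(settings$n_chains)) {
    set.seed(seed + 7919L * ch)
    x <- x0
    x[main] <- x0[main] + stats::rnorm(d_m, 0, 0.05)
    lpx <- lp_x(x)
    tries <- 0
    while (!is.finite(lpx) && tries < 100) {
      x[main] <- x0[main] + stats::rnorm(d_m, 0, 0.05)
      lpx <- lp_x(x); tries <- tries + 1
    }
    if (!is.finite(lpx)) stop("could not initialise chain near start point")

    # main block: adaptive random-walk Metropolis with empirical covariance
    # (diminishing adaptation); latent block: prior-reversible
    # Crank-Nicolson proposal whose mixing angle targets the same rate
    m <- x[main]
    C <- matrix(0, d_m, d_m)
    loglam <- -2
    L <- diag(d_m) * 0.05
    beta_cn <- 0.5
    n_acc <- 0; kept <- 0
    for (it in seq_len(settings$n_iter)) {
      xp <- x
      xp[main] <- x[main] + drop(L %*% stats::rnorm(d_m))
      lpp <- lp_x(xp)
      a <- if (is.finite(lpp)) min(1, exp(lpp - lpx)) else 0
      if (stats::runif(1) < a) { x <- xp; lpx <- lpp; n_acc <- n_acc + 1 }
      g <- 1 / (it + 1)
      dm <- x[main] - m
      m <- m + g * dm
      C <- C + g * (tcrossprod(dm) - C)
      loglam <- loglam +
        min(0.05, 1 / sqrt(it)) * (a - settings$target_accept)
      if (it %% 50 == 0) {
        S <- exp(loglam) * (2.38^2 / d_m) * (C + 1e-10 * diag(d_m))
        L <- tryCatch(t(chol(S)), error = function(e) L)
      }
      if (length(eps_i) > 0) {
        # Crank-Nicolson steps leave the N(0, sd^2) prior invariant, so the
        # acceptance ratio is the likelihood ratio alone (the eps prior
        # terms inside lp_x cancel the proposal asymmetry exactly); small
        # random sub-blocks keep acceptance workable at large process SDs
        ord <- sample(seq_along(eps_i))
        blocks <- split(ord, ceiling(seq_along(ord) / settings$eps_block))
        a_sum <- 0
        for (bl in blocks) {
          idx <- eps_i[bl]
          xe <- x
          xe[idx] <- sqrt(1 - beta_cn^2) * x[idx] +
            beta_cn * stats::rnorm(length(idx), 0, eps_sd[bl])
          lpe <- lp_x(xe)
          dprior <- sum(stats::dnorm(xe[idx], 0, eps_sd[bl], log = TRUE)) -
            sum(stats::dnorm(x[idx], 0, eps_sd[bl], log = TRUE))
          ae <- if (is.finite(lpe))
            min(1, exp(lpe - lpx - dprior)) else 0
          if (stats::runif(1) < ae) { x <- xe; lpx <- lpe }
          a_sum <- a_sum + ae
        }
        beta_cn <- min(0.999, max(1e-3, beta_cn *
          exp(min(0.1, 2 / sqrt(it)) *
                (a_sum / length(blocks) - 0.3))))
      }
      if (it > settings$n_burn &&
          (it - settings$n_burn) %% settings$thin == 0) {
        kept <- kept + 1
        row <- (ch - 1L) * n_keep + kept
        draws[row, ] <- to_natural(x, tt)
        lp_keep[row] <- lpx
        chain_id[row] <- ch
      }
    }
    accept[ch] <- n_acc / settings$n_iter
  }

  rh <- rhat_diag(draws, chain_id)
  names(rh) <- tt$names
  if (any(rh > settings$rhat_error, na.rm = TRUE))
    stop(sprintf("MCMC did not converge: max Rhat = %.3f (%s)",
                 max(rh, na.rm = TRUE), tt$names[which.max(rh)]))
  if (any(rh > settings$rhat_warn, na.rm = TRUE))
    warning(sprintf("Rhat above %.2f for: %s", settings$rhat_warn,
                    paste(tt$names[which(rh > settings$rhat_warn)],
                          collapse = ", ")))
  structure(
    list(draws = draws, chain = chain_id, lp = lp_keep, rhat = rh,
         accept = accept, spec = spec, settings = settings, seed = seed),
    class = "titi_fit")
}

#' @export
print.titi_fit <- function(x, ...) {
  cat(sprintf("titi_fit %s: %d draws (%d chains), accept %.2f, max Rhat %.3f\n",
              x$spec$name, nrow(x$draws), length(unique(x$chain)),
              mean(x$accept), max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

# iterate a function over draws of a fit or averaged object; fun receives
# (par, spec, eps_s, eps_f) and must return a numeric vector
each_draw <- function(fitobj, fun) {
  if (inherits(fitobj, "titi_fit")) {
    spec <- fitobj$spec
    has_es <- spec$sigma_s_proc > 0; has_ef <- spec$sigma_f_proc > 0
    lapply(seq_len(nrow(fitobj$draws)), function(i) {
      par <- fitobj$draws[i, ]
      fun(par, spec,
          if (has_es) unname(par[paste0("eps_s", 1:29)]) else NULL,
          if (has_ef) unname(par[paste0("eps_f", 1:30)]) else NULL)
    })
  } else if (inherits(fitobj, "titi_averaged")) {
    lapply(seq_len(nrow(fitobj$pick)), function(i) {
      f <- fitobj$fits[[fitobj$pick$model[i]]]
      spec <- f$spec
      par <- f$draws[fitobj$pick$draw[i], ]
      fun(par, spec,
          if (spec$sigma_s_proc > 0) unname(par[paste0("eps_s", 1:29)]) else NULL,
          if (spec$sigma_f_proc > 0) unname(par[paste0("eps_f", 1:30)]) else NULL)
    })
  } else stop("expected a titi_fit or titi_averaged object")
}

#' WAIC of a fitted model
#'
#' Computes the widely applicable information criterion on the deviance
#' scale, `W = -2 (lppd - p_waic)`, with the variance-based effective
#' parameter count. The pointwise partition treats every independent
#' likelihood factor as a data point: each CPUE observation plus the five
#' auxiliary constraints (configurable to CPUE-only).
#'
#' @param fitobj A [fit()] result.
#' @param inputs The [assessment_inputs()] bundle the model was fitted to.
#' @param points `"all"` (CPUE plus constraints) or `"cpue"`.
#' @return Object of class `titi_waic` with `lppd`, `p_waic`, `waic` and
#'   the pointwise log-likelihood matrix.
#' @export
compute_waic <- function(fitobj, inputs, points = c("all", "cpue")) {
  points <- match.arg(points)
  stopifnot(inherits(fitobj, "titi_fit"), nrow(fitobj$draws) >= 2)
  drivers <- apply_lags(inputs$covariates, fitobj$spec)
  rows <- each_draw(fitobj, function(par, spec, eps_s, eps_f) {
    res <- trajectory_core(par, drivers, inputs, eps_s, eps_f)
    if (!res$ok) stop("non-finite pointwise likelihood at a retained draw: ",
                      res$reason)
    pointwise_core(res, inputs, par[["k"]], par[["sigma_obs"]], par[["r_j"]])
  })
  ll <- do.call(rbind, rows)
  if (points == "cpue") ll <- ll[, seq_len(nrow(inputs$obs$cpue)), drop = FALSE]
  if (any(!is.finite(ll))) stop("non-finite pointwise log likelihood")
  # log of column means of exp(ll), stabilised
  mx <- apply(ll, 2, max)
  lppd_i <- mx + log(colMeans(exp(sweep(ll, 2, mx))))
  p_i <- apply(ll, 2, stats::var)
  structure(list(lppd = sum(lppd_i), p_waic = sum(p_i),
                 waic = -2 * (sum(lppd_i) - sum(p_i)),
                 pointwise = ll),
            class = "titi_waic")
}

#' WAIC-based model weights
#'
#' `w_m = exp(-0.5 dW_m) / sum_k exp(-0.5 dW_k)` with
#' `dW_m = W_m - min(W)`. Invariant to adding a constant to all `W`.
#'
#' @param W Numeric vector of WAIC values (finite, length >= 1).
#' @return Weights summing to one.
#' @export
model_weights <- function(W) {
  if (length(W) == 0) stop("empty WAIC list")
  if (any(!is.finite(W))) stop("non-finite WAIC values")
  dW <- W - min(W)
  w <- exp(-0.5 * dW)
  w / sum(w)
}

#' Model-selection table
#'
#' Orders models by WAIC (ties broken by canonical name) and attaches
#' `delta_w` and the WAIC weight, mirroring the usual selection-table
#' layout.
#'
#' @param waics Named list of [compute_waic()] results (or numeric WAICs).
#' @return Data frame with columns `model`, `W`, `delta_w`, `weight`.
#' @export
waic_table <- function(waics) {
  W <- vapply(waics, function(x) if (is.numeric(x)) x else x$waic, numeric(1))
  ord <- order(W, names(W))
  W <- W[ord]
  data.frame(model = names(W), W = unname(W),
             delta_w = unname(W - W[1]),
             weight = unname(model_weights(W)),
             row.names = NULL)
}

#' Pool posterior draws across models by WAIC weight
#'
#' Builds a model-averaged posterior of fixed size by allocating draws to
#' models with the deterministic largest-remainder rule on the weights and
#' resampling each model's retained draws. Only quantities with the same
#' interpretation in every model (trajectories, growth rates, CPUE
#' predictions, and parameters whose meaning does not depend on the lag
#' structure) may be summarised from the pooled set; link coefficients are
#' refused unless all pooled models share the identical lag on that axis.
#'
#' @param fits Named list of [fit()] results.
#' @param weights Weights aligned with `fits` (e.g. from [waic_table()]).
#' @param size Number of pooled draws (default 10000).
#' @param seed Integer seed for the resampling.
#' @return Object of class `titi_averaged`.
#' @export
model_average <- function(fits, weights, size = 10000L, seed = 1L) {
  stopifnot(length(fits) == length(weights), abs(sum(weights) - 1) < 1e-8)
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$spec$name, character(1))
  # largest-remainder allocation
  quota <- weights * size
  n_m <- floor(quota)
  rem <- size - sum(n_m)
  if (rem > 0) {
    ord <- order(quota - n_m, decreasing = TRUE)
    n_m[ord[seq_len(rem)]] <- n_m[ord[seq_len(rem)]] + 1
  }
  set.seed(seed)
  pick <- do.call(rbind, lapply(seq_along(fits), function(m) {
    if (n_m[m] == 0) return(NULL)
    data.frame(model = names(fits)[m],
               draw = sample.int(nrow(fits[[m]]$draws), n_m[m],
                                 replace = TRUE))
  }))
  lag_s <- vapply(fits, function(f) f$spec$lag_s, integer(1))
  lag_f <- vapply(fits, function(f) f$spec$lag_f, integer(1))
  shared <- Reduce(intersect, lapply(fits, function(f) colnames(f$draws)))
  if (length(unique(lag_s)) > 1) shared <- setdiff(shared, "beta_s")
  if (length(unique(lag_f)) > 1) shared <- setdiff(shared, "beta_f")
  structure(list(fits = fits, pick = pick, weights = weights,
                 shared = shared, seed = seed),
            class = "titi_averaged")
}

#' Extract a pooled (model-averaged) parameter column
#'
#' @param avg A [model_average()] object.
#' @param name Parameter name; must have the same interpretation in every
#'   pooled model.
#' @return Numeric vector of pooled draws.
#' @export
averaged_parameter <- function(avg, name) {
  stopifnot(inherits(avg, "titi_averaged"))
  if (!name %in% avg$shared)
    stop(sprintf(
      "'%s' is model-specific under differing lag structures; model averaging is inappropriate for it",
      name))
  vapply(seq_len(nrow(avg$pick)), function(i)
    avg$fits[[avg$pick$model[i]]]$draws[avg$pick$draw[i], name], numeric(1))
}

#' Boundary rule for extending the lag grid
#'
#' If the best-fitting model sits on the boundary of the lag grid spanned
#' by the fitted candidate set (on either axis), propose the model one lag
#' step beyond that boundary; otherwise propose nothing. Constant-rate
#' axes (`NoS`/`NoF`) never trigger an extension.
#'
#' @param wtab A [waic_table()].
#' @param specs Named list of the fitted [model_spec()]s.
#' @return List of new [model_spec()]s (possibly empty).
#' @export
expand_lag_grid <- function(wtab, specs) {
  best <- specs[[wtab$model[1]]]
  out <- list()
  lag_s <- vapply(specs, function(s) s$lag_s, integer(1))
  lag_f <- vapply(specs, function(s) s$lag_f, integer(1))
  if (!is.na(best$lag_s)) {
    grid <- sort(unique(lag_s[!is.na(lag_s)]))
    if (best$lag_s == min(grid))
      out[[length(out) + 1L]] <- model_spec(best$lag_s - 1L, best$lag_f)
    if (best$lag_s == max(grid))
      out[[length(out) + 1L]] <- model_spec(best$lag_s + 1L, best$lag_f)
  }
  if (!is.na(best$lag_f)) {
    grid <- sort(unique(lag_f[!is.na(lag_f)]))
    if (best$lag_f == min(grid))
      out[[length(out) + 1L]] <- model_spec(best$lag_s, best$lag_f - 1L)
    if (best$lag_f == max(grid))
      out[[length(out) + 1L]] <- model_spec(best$lag_s, best$lag_f + 1L)
  }
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Posterior predictive check for CPUE
#'
#' For every CPUE year, simulates a replicate observation
#' `I_rep ~ N(k n0_t, sigma_obs^2)` for each posterior draw and returns the
#' central 95% prediction interval together with whether the observed value
#' falls inside it.
#'
#' @param fitobj A [fit()] result or [model_average()] object.
#' @param inputs The matching [assessment_inputs()] bundle.
#' @param seed Integer seed for the replicate noise.
#' @param prob Interval coverage (default 0.95).
#' @return Data frame `year, t, observed, pred_mean, lo, hi, inside`.
#' @export
posterior_predictive_cpue <- function(fitobj, inputs, seed = 1L,
                                      prob = 0.95) {
  obs <- inputs$obs
  driv_cache <- new.env()
  get_drivers <- function(spec) {
    if (is.null(driv_cache[[spec$name]]))
      driv_cache[[spec$name]] <- apply_lags(inputs$covariates, spec)
    driv_cache[[spec$name]]
  }
  set.seed(seed)
  rep_mat <- each_draw(fitobj, function(par, spec, eps_s, eps_f) {
    res <- trajectory_core(par, get_drivers(spec), inputs, eps_s, eps_f)
    if (!res$ok) stop(res$reason)
    mu <- par[["k"]] * res$n[1, obs$cpue$t]
    stats::rnorm(length(mu), mu, par[["sigma_obs"]])
  })
  rep_mat <- do.call(rbind, rep_mat)
  a <- (1 - prob) / 2
  lo <- apply(rep_mat, 2, stats::quantile, probs = a)
  hi <- apply(rep_mat, 2, stats::quantile, probs = 1 - a)
  data.frame(year = obs$cpue$year, t = obs$cpue$t, observed = obs$cpue$cpue,
             pred_mean = colMeans(rep_mat), lo = lo, hi = hi,
             inside = obs$cpue$cpue >= lo & obs$cpue$cpue <= hi,
             row.names = NULL)
}

#' Fit the process-error variant of a model
#'
#' Augments the parameter vector with year-specific logit-scale
#' disturbances `eps_s[t] ~ N(0, sigma_s^2)` on the survival link and
#' `eps_f[t] ~ N(0, sigma_f^2)` on the fecundity link; the rest of the
#' pipeline is unchanged.
#'
#' @param spec A [model_spec()] (its process SDs are replaced).
#' @param sigma_s,sigma_f Process-error SDs (> 0), e.g. from
#'   [solve_process_sigma()].
#' @inheritParams fit
#' @return A `titi_fit` object.
#' @export
fit_with_process_error <- function(spec, sigma_s, sigma_f, inputs,
                                   settings = mcmc_settings(), seed = 1L,
                                   init = "auto") {
  stopifnot(sigma_s > 0, sigma_f > 0)
  spec2 <- model_spec(spec$lag_s, spec$lag_f, sigma_s, sigma_f)
  fit(spec2, inputs, settings, seed, init)
}
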