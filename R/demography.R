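#' Age-specific maturity probabilities
#'
#' The probability that an individual in age class `i` is sexually mature is
#' zero for classes 0--2, one for classes 13 and 14 (the plus group), and
#' follows a probit-linear curve `pnorm((i - mu_p) / sigma_p)` for classes
#' 3--12, where `mu_p` and `sigma_p` are the mean and standard deviation of
#' age at maturity.
#'
#' @param mu_p Mean age at maturity (years).
#' @param sigma_p Standard deviation of age at maturity (years, > 0).
#' @return Numeric vector of length 15, `p[i + 1]` for age class `i`.
#' @export
maturity_probabilities <- function(mu_p, sigma_p) {
  if (!is.finite(sigma_p) || sigma_p <= 0) stop("sigma_p must be > 0")
  p <- numeric(15L)
  p[4:13] <- stats::pnorm((3:12 - mu_p) / sigma_p)
  p[14:15] <- 1
  p
}

#' Logistic climate link for a vital rate
#'
#' Vital rates are tied to the annual climate covariate through a scaled
#' logistic: `rate_max / (1 + exp(-(alpha + beta * z)))`. The rate is
#' strictly inside `(0, rate_max)` and is monotone in `z` with the sign of
#' `beta`.
#'
#' @param alpha,beta Logit-scale intercept and slope.
#' @param z Climate covariate (vectorised).
#' @param rate_max Upper bound of the rate, in `(0, 1]`.
#' @return Rate value(s), same length as `z`.
#' @export
logistic_vital_rate <- function(alpha, beta, z, rate_max) {
  if (!is.finite(rate_max) || rate_max <= 0 || rate_max > 1)
    stop("rate_max must be in (0, 1]")
  rate_max * stats::plogis(alpha + beta * z)
}

#' Juvenile survival as a proportion of adult survival
#'
#' Juvenile survival (age classes 0 and 1) is `r * s_a`, with the scaling
#' `r` in `[0, 1]` estimated during fitting; juvenile survival therefore
#' inherits the adult climate link.
#'
#' @param r Juvenile-to-adult survival ratio in `[0, 1]`.
#' @param s_a Adult survival in `(0, 1)` (vectorised).
#' @return `r * s_a`.
#' @export
juvenile_survival <- function(r, s_a) {
  if (!is.finite(r) || r < 0 || r > 1) stop("r must be in [0, 1]")
  if (any(!is.finite(s_a) | s_a <= 0 | s_a >= 1))
    stop("s_a must be in (0, 1)")
  r * s_a
}

#' Leslie matrix for the age-structured model
#'
#' Builds the 15 x 15 projection matrix used only to derive the stable-age
#' distribution that seeds the run-in. The top row is chick production,
#' `0.5 * (1 - w) * f * p_i` (one egg per pair, a fraction `w` of attempts
#' lost to weka, only mature birds breed). Sub-diagonal survival entries
#' mirror the projection equations: the juvenile rate carries classes 0 and
#' 1 forward, the adult rate carries classes 2--13, and the plus group
#' retains survivors with a self-loop at (14, 14). Harvest and bycatch are
#' not part of the initializer matrix.
#'
#' @param s_a Adult survival in (0, 1).
#' @param s_j Juvenile survival in (0, 1).
#' @param f Fecundity (chicks per adult) in (0, f_max].
#' @param p Maturity vector from [maturity_probabilities()].
#' @param constants A [fixed_constants()] object (supplies `w`).
#' @return A 15 x 15 numeric matrix.
#' @export
build_leslie_matrix <- function(s_a, s_j, f, p, constants = fixed_constants()) {
  stopifnot(length(p) == 15L, s_a > 0, s_a < 1, s_j > 0, s_j < 1, f >= 0)
  M <- matrix(0, 15L, 15L)
  M[1, ] <- 0.5 * (1 - constants$w) * f * p
  M[2, 1] <- s_j
  M[3, 2] <- s_j
  for (i in 4:15) M[i, i - 1] <- s_a
  M[15, 15] <- s_a
  if (any(!is.finite(M))) stop("non-finite entries in Leslie matrix")
  M
}

#' Stable age distribution of a projection matrix
#'
#' The right eigenvector of the dominant eigenvalue, normalised to sum to
#' one. Degenerate (reducible) matrices whose dominant eigenvector places
#' essentially no mass on most classes are rejected.
#'
#' @param M A non-negative projection matrix.
#' @return List with `vector` (unit-sum age distribution) and `lambda`
#'   (dominant eigenvalue).
#' @export
stable_age_distribution <- function(M) {
  e <- eigen(M)
  i <- which.max(Mod(e$values))
  lambda <- e$values[i]
  if (abs(Im(lambda)) > 1e-8 * Mod(lambda))
    stop("dominant eigenvalue is complex; matrix is not a valid projection")
  v <- Re(e$vectors[, i])
  if (sum(v) < 0) v <- -v
  if (any(v < -1e-10 * max(abs(v))))
    stop("dominant eigenvector has negative entries")
  v[v < 0] <- 0
  v <- v / sum(v)
  if (min(v) < 1e-12)
    stop("degenerate stable-age distribution; matrix appears reducible")
  list(vector = v, lambda = Re(lambda))
}

# One projection transition shared by run-in and projection proper.
# v: age vector; returns the next-year vector given rates and the chick
# removal (harvest) already expressed as a count h_count.
step_core <- function(v, s_a, s_j, f_next, b, h_count, p, w) {
  surv <- 1 - b
  nn <- numeric(15L)
  nn[2] <- surv * s_j * (v[1] - h_count)
  nn[3] <- surv * s_j * v[2]
  nn[4:14] <- surv * s_a * v[3:13]
  nn[15] <- surv * s_a * (v[14] + v[15])
  nn[1] <- 0.5 * (1 - w) * f_next * sum(p * nn)
  nn
}

#' Five-year run-in to equilibrate the age structure
#'
#' The stable-age vector of the initializer Leslie matrix is projected for
#' `run_in_years` transitions with survival, fecundity, harvest and bycatch
#' held at their year-1 (1976) values, harvest and bycatch being expressed
#' as constant *rates* `h` and `b`. Because the run-in map is linear in the
#' abundance vector, the result is rescaled at the end so that the adult
#' total in model year 1 equals `N1a`.
#'
#' @param u Starting age vector (any scale, e.g. a unit-sum stable-age
#'   distribution).
#' @param N1a Adults in model year 1 (individuals).
#' @param s_a,s_j,f Year-1 vital rates.
#' @param h Constant chick-harvest rate in `[0, 1)`.
#' @param b Constant bycatch rate in `[0, 1)`.
#' @param p Maturity vector.
#' @param constants A [fixed_constants()] object.
#' @param steps Number of run-in transitions (default from `constants`).
#' @return Age vector (length 15) for model year 1, scaled to `N1a` adults.
#' @export
run_in <- function(u, N1a, s_a, s_j, f, h, b, p,
                   constants = fixed_constants(),
                   steps = constants$run_in_years) {
  if (h >= 1 || h < 0) stop("run-in harvest rate h must be in [0, 1)")
  if (b >= 1 || b < 0) stop("run-in bycatch rate b must be in [0, 1)")
  v <- u
  if (steps > 0) {
    for (k in seq_len(steps))
      v <- step_core(v, s_a, s_j, f, b, h * v[1], p, constants$w)
  }
  adults <- sum(p * v)
  if (adults <= 0) stop("run-in produced no adults")
  v * (N1a / adults)
}

# Internal projection core. Returns list(ok=FALSE, reason=...) instead of
# throwing, so the posterior hot path can map failures to -Inf cheaply.
project_core <- function(n1, s_a, s_j, f, H, B, p, w, n_years = 30L) {
  nT <- n_years
  n <- matrix(0, 15L, nT)
  n[, 1] <- n1
  N <- numeric(nT); Na <- numeric(nT)
  N[1] <- sum(n1); Na[1] <- sum(p * n1)
  b <- numeric(nT - 1L); h <- numeric(nT - 1L)
  for (t in seq_len(nT - 1L)) {
    v <- n[, t]
    if (!is.finite(N[t]))
      return(list(ok = FALSE, reason = "non-finite abundance"))
    if (B[t] >= N[t])
      return(list(ok = FALSE,
                  reason = sprintf("bycatch B_%d >= population N_%d", t, t)))
    if (H[t] > v[1])
      return(list(ok = FALSE,
                  reason = sprintf("harvest H_%d exceeds chicks n0_%d", t, t)))
    b[t] <- B[t] / N[t]
    h[t] <- if (v[1] > 0) H[t] / v[1] else 0
    nn <- step_core(v, s_a[t], s_j[t], f[t + 1L], b[t], H[t], p, w)
    n[, t + 1L] <- nn
    N[t + 1L] <- sum(nn)
    Na[t + 1L] <- sum(p * nn)
  }
  list(ok = TRUE, n = n, N = N, N_a = Na, b = b, h = h)
}

#' Project the population forward under harvest, bycatch and weka pressure
#'
#' Implements the five projection equations: chicks are produced as
#' `n0 = 0.5 (1 - w) f N_a`; harvested chicks are removed immediately after
#' the census and before first-year survival; every survival transition is
#' multiplied by `(1 - b_t)` with `b_t = B_t / N_t` (all birds equally
#' vulnerable to bycatch); and the plus group accumulates classes 13 and 14.
#'
#' @param n1 Age vector for model year 1 (individuals), e.g. from
#'   [run_in()].
#' @param s_a,s_j Adult and juvenile survival for transitions
#'   `t = 1 .. n_years - 1`.
#' @param f Fecundity for years `t = 1 .. n_years`.
#' @param H,B Harvest and bycatch counts for `t = 1 .. n_years - 1`.
#' @param p Maturity vector.
#' @param constants A [fixed_constants()] object.
#' @return An object of class `titi_trajectory`: abundance matrix `n`
#'   (15 x n_years), totals `N`, adults `N_a`, realised rates `s_a`, `s_j`,
#'   `f`, bycatch proportions `b`, harvest proportions `h`, and calendar
#'   `years`.
#' @export
project <- function(n1, s_a, s_j, f, H, B, p, constants = fixed_constants()) {
  nT <- constants$n_years
  stopifnot(length(n1) == 15L, length(f) >= nT,
            length(s_a) >= nT - 1L, length(s_j) >= nT - 1L,
            length(H) >= nT - 1L, length(B) >= nT - 1L)
  if (any(H < 0) || any(B < 0)) stop("harvest and bycatch must be >= 0")
  res <- project_core(n1, s_a, s_j, f, H, B, p, constants$w, nT)
  if (!res$ok) stop(res$reason)
  structure(
    list(n = res$n, N = res$N, N_a = res$N_a,
         s_a = s_a[seq_len(nT - 1L)], s_j = s_j[seq_len(nT - 1L)],
         f = f[seq_len(nT)], b = res$b, h = res$h,
         years = model_year_to_calendar(seq_len(nT))),
    class = "titi_trajectory")
}

#' @export
print.titi_trajectory <- function(x, ...) {
  cat(sprintf(
    "titi population trajectory %d-%d\n  total %0.1fM -> %0.1fM (%+.2f%%/yr)\n",
    x$years[1], x$years[length(x$years)],
    x$N[1] / 1e6, x$N[length(x$N)] / 1e6,
    100 * ((x$N[length(x$N)] / x$N[1])^(1 / (length(x$N) - 1)) - 1)))
  invisible(x)
}
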