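# Independent oracles, written as plain scalar loops so they share no code
# path with the package internals they check.

# hand-looped age-structured projection
oracle_project <- function(n1, s_a, s_j, f, H, B, p, w, nT) {
  n <- matrix(0, 15, nT)
  n[, 1] <- n1
  for (t in 1:(nT - 1)) {
    Nt <- 0
    for (i in 1:15) Nt <- Nt + n[i, t]
    bt <- B[t] / Nt
    nxt <- rep(0, 15)
    nxt[2] <- (1 - bt) * s_j[t] * (n[1, t] - H[t])
    nxt[3] <- (1 - bt) * s_j[t] * n[2, t]
    for (i in 4:14) nxt[i] <- (1 - bt) * s_a[t] * n[i - 1, t]
    nxt[15] <- (1 - bt) * s_a[t] * (n[14, t] + n[15, t])
    Na <- 0
    for (i in 1:15) Na <- Na + p[i] * nxt[i]
    nxt[1] <- 0.5 * (1 - w) * f[t + 1] * Na
    n[, t + 1] <- nxt
  }
  n
}

# hand-looped run-in with constant rates, rescaled to N1a adults at the end
oracle_run_in <- function(u, N1a, s_a, s_j, f, h, b, p, w, steps) {
  v <- u
  if (steps > 0) for (k in 1:steps) {
    nxt <- rep(0, 15)
    nxt[2] <- (1 - b) * s_j * (v[1] - h * v[1])
    nxt[3] <- (1 - b) * s_j * v[2]
    for (i in 4:14) nxt[i] <- (1 - b) * s_a * v[i - 1]
    nxt[15] <- (1 - b) * s_a * (v[14] + v[15])
    Na <- 0
    for (i in 1:15) Na <- Na + p[i] * nxt[i]
    nxt[1] <- 0.5 * (1 - w) * f * Na
    v <- nxt
  }
  adults <- sum(p * v)
  v * N1a / adults
}

# power-method dominant eigenpair
oracle_power_iteration <- function(M, iters = 500) {
  v <- rep(1, nrow(M)) / nrow(M)
  lambda <- NA_real_
  for (i in 1:iters) {
    w <- as.numeric(M %*% v)
    lambda <- sum(w) / sum(v)
    v <- w / sum(w)
  }
  list(vector = v, lambda = lambda)
}

# a small monthly SOI table with given values for the given years
make_soi <- function(years, values) {
  monthly_soi(data.frame(year = rep(years, each = 12),
                         month = rep(1:12, length(years)),
                         soi = values))
}

# plausible random parameters for projection property tests
random_projection_case <- function() {
  nT <- 30
  list(
    n1 = runif(15, 1e4, 5e6),
    s_a = runif(nT - 1, 0.85, 0.975),
    s_j = runif(nT - 1, 0.4, 0.7),
    f = runif(nT, 0.3, 0.6),
    H = runif(nT - 1, 0, 1e4),
    B = runif(nT - 1, 0, 1e4),
    p = titipop::maturity_probabilities(runif(1, 6, 9), runif(1, 1.2, 2.5)),
    w = runif(1, 0, 0.2))
}

# one cached paper-scale synthetic bundle shared across test files
paperlike_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- titipop::generate_dataset(
      titipop::preset_paperlike(1))
    cache
  }
})

# tiny MCMC settings for fast fits in tests
tiny_settings <- function(n_iter = 3000, n_burn = 1500, thin = 5) {
  titipop::mcmc_settings(n_iter = n_iter, n_burn = n_burn, thin = thin,
                         rhat_warn = Inf, rhat_error = Inf)
}

# a small fake posterior around the truth of a dataset, for draw-iterating
# functions whose statistical behaviour is tested elsewhere
fake_fit <- function(ds, n = 50, jitter = 0.02, seed = 99) {
  set.seed(seed)
  par <- ds$truth$params
  nm <- names(par)
  draws <- t(vapply(seq_len(n), function(i)
    par * exp(rnorm(length(par), 0, jitter)), numeric(length(par))))
  colnames(draws) <- nm
  structure(list(draws = draws, chain = rep(1L, n), lp = rep(0, n),
                 rhat = setNames(rep(1, length(nm)), nm), accept = 0.3,
                 spec = ds$truth$spec,
                 settings = tiny_settings(), seed = seed),
            class = "titi_fit")
}
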