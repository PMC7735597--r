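test_that("maturity curve is probit-linear with hard young/old plateaus", {
  p <- maturity_probabilities(7.5, 1.9)
  expect_equal(p[1:3], rep(0, 3))
  expect_equal(p[14:15], rep(1, 2))
  expect_equal(p[8], pnorm((7 - 7.5) / 1.9))
  expect_true(all(diff(p) >= 0))

  p2 <- maturity_probabilities(7, 0.4)
  expect_equal(p2[8], 0.5)  # age class 7 at the mean is the median

  # independent normal-CDF evaluation by quadrature
  phi <- integrate(function(x) dnorm(x), -Inf, (7 - 7.5) / 1.9)$value
  expect_equal(maturity_probabilities(7.5, 1.9)[8], phi, tolerance = 1e-8)

  expect_error(maturity_probabilities(7.5, 0), "sigma_p")
})

test_that("logistic vital-rate link saturates at the configured maximum", {
  expect_equal(logistic_vital_rate(0, 0, 0, 0.98), 0.49)
  z <- seq(-3, 3, length.out = 7)
  expect_equal(logistic_vital_rate(1.2, 0, z, 0.9),
               rep(0.9 * plogis(1.2), 7))
  # direct exponential evaluation
  expect_equal(logistic_vital_rate(3, 0.5, 0, 0.98),
               0.98 / (1 + exp(-3)))
  r <- logistic_vital_rate(0.3, 0.8, z, 0.98)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 0.98))
  expect_error(logistic_vital_rate(0, 0, 0, 1.5), "rate_max")
})

test_that("juvenile survival is the scaled adult rate", {
  expect_equal(juvenile_survival(1, 0.95), 0.95)
  expect_equal(juvenile_survival(0, 0.95), 0)
  expect_equal(juvenile_survival(0.7, 0.95), 0.665)
  expect_error(juvenile_survival(1.2, 0.9), "r must")
  expect_error(juvenile_survival(0.5, 1.1), "s_a")
})

test_that("Leslie matrix has the projection-equation sparsity pattern", {
  p <- maturity_probabilities(7.5, 1.9)
  M <- build_leslie_matrix(0.95, 0.665, 0.52, p)
  expect_equal(dim(M), c(15L, 15L))
  expect_equal(M[2, 1], 0.665)
  expect_equal(M[3, 2], 0.665)
  for (i in 4:15) expect_equal(M[i, i - 1], 0.95)
  expect_equal(M[15, 15], 0.95)
  expect_equal(M[1, ], 0.5 * (1 - 0.11) * 0.52 * p)
  # exactly 14 sub-diagonal entries + plus-group loop + top-row pattern
  off <- M; off[1, ] <- 0; diag(off) <- 0
  expect_equal(sum(off != 0), 14)
  M0 <- build_leslie_matrix(0.95, 0.665, 1e-12, p)
  expect_equal(max(M0[1, ]), 0.5 * 0.89 * 1e-12 * 1)

  # 3-class toy analogue with survivals 0.5, plus-loop 0.5 and fecundities
  # chosen so the dominant eigenvalue is 1 (0.25 + 0.5 * (0.5 + 1.0) = 1),
  # verified against the characteristic-polynomial root
  A <- rbind(c(0.25, 0.5, 1.0), c(0.5, 0, 0), c(0, 0.5, 0.5))
  lam <- max(Mod(eigen(A)$values))
  cp <- function(l) det(A - l * diag(3))
  expect_lt(abs(cp(1)), 1e-12)
  expect_equal(lam, 1, tolerance = 1e-10)
})

test_that("stable age distribution is the dominant eigenvector", {
  p <- maturity_probabilities(7.5, 1.9)
  M <- build_leslie_matrix(0.95, 0.665, 0.52, p)
  sad <- stable_age_distribution(M)
  expect_equal(sum(sad$vector), 1)
  expect_true(all(sad$vector >= 0))
  # one projection step multiplies the vector by lambda
  step <- as.numeric(M %*% sad$vector)
  expect_lt(max(abs(step - sad$lambda * sad$vector)) / max(step), 1e-8)
  # agreement with a 500-step power iteration
  pow <- oracle_power_iteration(M)
  expect_equal(sad$vector, pow$vector, tolerance = 1e-10)
  expect_equal(sad$lambda, pow$lambda, tolerance = 1e-10)
  # reducible pure plus-loop matrix is rejected
  D <- matrix(0, 15, 15); D[15, 15] <- 1
  expect_error(stable_age_distribution(D), "reducible|negative|complex")
})

test_that("run-in equilibrates and rescales to the target adult count", {
  p <- maturity_probabilities(7.5, 1.9)
  cst <- fixed_constants()
  u <- stable_age_distribution(build_leslie_matrix(0.95, 0.665, 0.52, p,
                                                   cst))$vector
  # zero steps: scaled input
  v0 <- run_in(u, 2e7, 0.93, 0.6, 0.5, 0.1, 0.01, p, cst, steps = 0)
  expect_equal(v0, u * 2e7 / sum(p * u))
  # scale invariance of the input vector (linearity + final rescale)
  v1 <- run_in(u, 2e7, 0.93, 0.6, 0.5, 0.1, 0.01, p, cst)
  v2 <- run_in(5 * u, 2e7, 0.93, 0.6, 0.5, 0.1, 0.01, p, cst)
  expect_equal(v1, v2)
  expect_equal(sum(p * v1), 2e7)
  # 5-step hand-looped oracle
  vo <- oracle_run_in(u, 2e7, 0.93, 0.6, 0.5, 0.1, 0.01, p, cst$w, 5)
  expect_equal(v1, vo, tolerance = 1e-12)
  expect_error(run_in(u, 2e7, 0.93, 0.6, 0.5, 1, 0.01, p, cst), "h must")
  expect_error(run_in(u, 2e7, 0.93, 0.6, 0.5, 0.1, 1.2, p, cst), "b must")
})

test_that("projection equations match a hand-computed two-step toy", {
  p <- c(0, 0, 0, rep(0.5, 10), 1, 1)
  n1 <- rep(1000, 15)
  s_a <- rep(0.9, 29); s_j <- rep(0.5, 29); f <- rep(0.4, 30)
  H <- rep(50, 29); B <- rep(300, 29)  # N = 15000 in year 1 so b_1 = 0.02
  # a short horizon keeps the declining toy population above its constant
  # forcing counts
  tr <- project(n1, s_a, s_j, f, H, B, p, fixed_constants(n_years = 5L))
  # year 2 by hand: survivor factor (1 - 0.02)
  expect_equal(tr$n[2, 2], 0.98 * 0.5 * (1000 - 50))
  expect_equal(tr$n[3, 2], 0.98 * 0.5 * 1000)
  expect_equal(tr$n[4, 2], 0.98 * 0.9 * 1000)
  expect_equal(tr$n[15, 2], 0.98 * 0.9 * 2000)
  Na2 <- sum(p * c(0, tr$n[2:15, 2]))
  expect_equal(tr$n[1, 2], 0.5 * (1 - 0.11) * 0.4 * Na2)
  expect_equal(tr$b[1], 0.02)
  expect_equal(tr$h[1], 0.05)
})

test_that("projection limiting cases behave as the equations demand", {
  p <- maturity_probabilities(7.5, 1.9)
  n1 <- runif(15, 1e3, 1e5)
  # no reproduction: chicks are zero from year 2 on
  tr <- project(n1, rep(0.9, 29), rep(0.5, 29), rep(0, 30),
                rep(0, 29), rep(0, 29), p)
  expect_equal(tr$n[1, 2:30], rep(0, 29))
  # total chick harvest: the following year-1 class is empty
  H <- rep(0, 29); H[1] <- n1[1]
  tr2 <- project(n1, rep(0.9, 29), rep(0.5, 29), rep(0.4, 30),
                 H, rep(0, 29), p)
  expect_equal(tr2$n[2, 2], 0)
  # harvest above chicks / bycatch above population are rejected
  expect_error(project(n1, rep(0.9, 29), rep(0.5, 29), rep(0.4, 30),
                       rep(2 * max(n1), 29), rep(0, 29), p), "harvest")
  expect_error(project(n1, rep(0.9, 29), rep(0.5, 29), rep(0.4, 30),
                       rep(0, 29), rep(1e9, 29), p), "bycatch")
})

test_that("projection satisfies the accounting identity and cohort decay", {
  set.seed(21)
  for (rep in 1:25) {
    cs <- random_projection_case()
    tr <- project(cs$n1, cs$s_a, cs$s_j, cs$f, cs$H, cs$B, cs$p,
                  fixed_constants(w = cs$w))
    # independent loop oracle
    no <- oracle_project(cs$n1, cs$s_a, cs$s_j, cs$f, cs$H, cs$B, cs$p,
                         cs$w, 30)
    expect_equal(tr$n, no, tolerance = 1e-13)
    # accounting identity at every transition
    for (t in 1:29) {
      lhs <- tr$N[t + 1] - tr$n[1, t + 1]
      rhs <- (1 - tr$b[t]) *
        (cs$s_j[t] * (tr$n[1, t] - cs$H[t] + tr$n[2, t]) +
           cs$s_a[t] * sum(tr$n[3:15, t]))
      expect_equal(lhs, rhs, tolerance = 1e-12)
    }
  }
  # with no harvest, bycatch, weka or reproduction, cohorts decay exactly
  p <- maturity_probabilities(7.5, 1.9)
  n1 <- rep(1e4, 15)
  tr <- project(n1, rep(0.9, 29), rep(0.5, 29), rep(0, 30),
                rep(0, 29), rep(0, 29), p, fixed_constants(w = 1e-9))
  expect_true(all(diff(tr$N) <= 0))
  expect_equal(tr$n[4, 2], 0.9 * n1[3])
  expect_equal(tr$n[3, 2], 0.5 * n1[2])
})

test_that("trajectory scales linearly with initial abundance", {
  ds <- paperlike_dataset()
  par <- ds$truth$params
  # express forcing as rates so the comparison is scale-free
  tr1 <- project_population(par, ds$truth$spec, ds$inputs)
  inp2 <- ds$inputs
  c_scale <- 2.5
  par2 <- par; par2[["N1a"]] <- par[["N1a"]] * c_scale
  inp2$forcing$H <- ds$inputs$forcing$H * c_scale
  inp2$forcing$B <- ds$inputs$forcing$B * c_scale
  tr2 <- project_population(par2, ds$truth$spec, inp2)
  expect_equal(tr2$n, c_scale * tr1$n, tolerance = 1e-10)
})
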