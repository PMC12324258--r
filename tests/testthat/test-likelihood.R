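test_that("implied covariance reduces to the textbook special cases", {
  st1 <- make_structure("cholesky", 1)
  G <- matrix(c(1, 0.04, 0.04, 1), 2)
  S <- implied_sigma(st1, c(sqrt(0.5), sqrt(0.5)), G)
  expect_equal(S, 0.5 * G + 0.5 * diag(2), tolerance = 1e-12)

  # rGE enabled but zero: identical to the independence model elementwise
  st <- make_structure("ip", 2, nA = 1, nE = 1, rge = TRUE)
  st0 <- make_structure("ip", 2, nA = 1, nE = 1)
  th0 <- c(0.5, 0.4, 0.3, 0.35, 0.6, 0.55, 0.4, 0.45)
  expect_equal(implied_sigma(st, c(th0, 0), G),
               implied_sigma(st0, th0, G), tolerance = 1e-14)

  # scalar rGE expansion: 0.36 + 0.64 + 2*0.24 = 1.48
  stt <- make_structure("ip", 1, nA = 1, nE = 1, rge = TRUE)
  stt$A$specific_free[1] <- FALSE
  stt$E$specific_free[1] <- FALSE
  expect_equal(as.numeric(implied_sigma(stt, c(0.6, 0.8, atanh(0.5)),
                                        matrix(1, 1, 1))), 1.48,
               tolerance = 1e-12)
})

test_that("the literal per-kernel cross-term convention is honoured and guarded", {
  st <- make_structure("ip", 2, nA = 1, nE = 1, rge = TRUE)
  th <- c(0.5, 0.4, 0.3, 0.35, 0.6, 0.55, 0.4, 0.45, atanh(0.5))
  # G = I: the literal form is symmetric and matches the per-individual block
  S <- implied_sigma(st, th, diag(3), cross_kernel = "literal")
  expect_equal(S, implied_sigma(st, th, diag(3)), tolerance = 1e-12)
  # off-diagonal relatedness makes the literal form asymmetric -> error
  G <- matrix(c(1, 0.05, 0.05, 1), 2)
  expect_error(implied_sigma(st, th, G, cross_kernel = "literal"),
               "asymmetric")
})

test_that("direct log-likelihood matches a naive dense MVN oracle", {
  set.seed(31)
  # standard normal density at the origin
  st1 <- make_structure("cholesky", 1)
  expect_equal(loglik_direct(st1, c(0, 1), matrix(0, 1, 1), matrix(1, 1, 1)),
               -0.5 * log(2 * pi), tolerance = 1e-12)

  st <- make_structure("cholesky", 2)
  th <- c(0.7, 0.2, 0.5, 0.6, -0.1, 0.7)
  n <- 6
  G <- small_grm(n = 40, m = 400, seed = 19)$values[1:n, 1:n]
  Y <- matrix(rnorm(n * 2), n, 2)
  S <- implied_sigma(st, th, G)
  expect_equal(loglik_direct(st, th, Y, G),
               naive_mvn_loglik(as.vector(Y), S), tolerance = 1e-10)

  # a fully missing trait marginalises exactly to the reduced model
  Y2 <- Y; Y2[, 2] <- NA
  expect_equal(loglik_direct(st, th, Y2, G),
               loglik_direct(st1, c(0.7, 0.6), Y[, 1, drop = FALSE], G),
               tolerance = 1e-10)
})

test_that("rotated fast path equals the dense path on complete data", {
  set.seed(41)
  G <- small_grm(n = 40, m = 400, seed = 19)
  for (r in 1:20) {
    k <- sample(2:4, 1)
    inst <- random_ip_instance(k, rge = r %% 2 == 0)
    Y <- matrix(rnorm(40 * k), 40, k)
    expect_equal(loglik_rotated(inst$structure, inst$theta, Y, G),
                 loglik_direct(inst$structure, inst$theta, Y, G$values),
                 tolerance = 1e-8)
  }
  # G = I: rotated likelihood is a sum of identical-covariance densities
  inst <- random_ip_instance(2)
  Y <- matrix(rnorm(20), 10, 2)
  gI <- grm(diag(10))
  ker <- latentgrm:::sigma_kernels(inst$structure, inst$theta)
  byrow <- sum(apply(Y, 1, function(y) naive_mvn_loglik(y, ker$CG + ker$CI)))
  expect_equal(loglik_rotated(inst$structure, inst$theta, Y, gI), byrow,
               tolerance = 1e-8)
  # missing data are refused on the fast path
  Yna <- Y; Yna[1, 1] <- NA
  expect_error(loglik_rotated(inst$structure, inst$theta, Yna, gI),
               "missing")
})

test_that("univariate fast path reduces to per-eigenvalue GREML variances", {
  G <- small_grm(n = 60, m = 500, seed = 23)
  y <- rnorm(60)
  st1 <- make_structure("cholesky", 1)
  a <- 0.6; e <- 0.7
  ytil <- crossprod(G$eigen$vectors, y)
  d <- G$eigen$values
  v <- a^2 * d + e^2
  expect_equal(loglik_rotated(st1, c(a, e), matrix(y), G),
               sum(-0.5 * log(2 * pi * v) - 0.5 * ytil^2 / v),
               tolerance = 1e-8)
})

test_that("maximum-likelihood fits recover simulated parameters", {
  G <- small_grm(n = 300, m = 2000, seed = 7)
  st <- make_structure("cholesky", 2)
  theta <- c(0.6, 0.25, 0.45, 0.65, 0.15, 0.7)
  sc <- simulation_scenario(st, theta, 300, seed = 92)
  Y <- simulate_phenotypes(sc, G)$values
  f <- grmsem_fit(Y, G, st, n_restarts = 2, seed = 3)
  expect_true(f$optim_ok)
  expect_equal(f$path, "rotated")
  # estimates within 3 SEs at this modest n
  expect_true(all(abs(f$theta_natural - theta) < 3 * pmax(f$se, 0.05)))
  # vcov is symmetric PSD
  expect_lt(max(abs(f$vcov_theta - t(f$vcov_theta))), 1e-10)
  expect_gte(min(eigen(f$vcov_theta, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
})

test_that("missing data trigger the dense path and remain fittable", {
  G <- small_grm(n = 150, m = 1500, seed = 55)
  st <- make_structure("cholesky", 2)
  theta <- c(0.6, 0.2, 0.5, 0.7, 0.1, 0.6)
  sc <- simulation_scenario(st, theta, 150, missing_rate = 0.18, seed = 77)
  Y <- simulate_phenotypes(sc, G)$values
  expect_gt(mean(is.na(Y)), 0.1)
  f <- grmsem_fit(Y, G, st, n_restarts = 1, seed = 5, compute_se = FALSE)
  expect_equal(f$path, "direct")
  expect_true(f$optim_ok)
  expect_equal(f$n_observations, sum(!is.na(Y)))
  # the dense fit agrees with a rotated fit on the same data sans missingness
  Yc <- simulate_phenotypes(simulation_scenario(st, theta, 150, seed = 77),
                            G)$values
  fc <- grmsem_fit(Yc, G, st, n_restarts = 1, seed = 5, compute_se = FALSE,
                   path = "direct")
  fr <- grmsem_fit(Yc, G, st, n_restarts = 1, seed = 5, compute_se = FALSE,
                   path = "rotated")
  expect_equal(fc$loglik, fr$loglik, tolerance = 1e-6)
})

test_that("G = I leaves A and E unidentified and is flagged", {
  set.seed(71)
  n <- 120
  Y <- matrix(rnorm(n * 2), n, 2)
  st <- make_structure("cholesky", 2)
  f <- grmsem_fit(Y, grm(diag(n)), st, n_restarts = 1, seed = 2)
  expect_false(f$converged)
  expect_true(any(grepl("near-singular", f$diagnostic)))
})

test_that("univariate heritability fit behaves across the h2 range", {
  G <- small_grm(n = 300, m = 2000, seed = 7)
  st1 <- make_structure("cholesky", 1)
  # pure genetic signal: a multiple of the top eigenvector pushes h2 to 1
  ytop <- G$eigen$vectors[, 1] * 3
  f1 <- fit_univariate_h2(ytop, G, n_restarts = 1, compute_se = FALSE)
  expect_gt(f1$h2, 0.95)
  # null truth: estimate near the boundary, one-sided p not significant
  sc0 <- simulation_scenario(st1, c(0, 1), 300, seed = 13)
  y0 <- simulate_phenotypes(sc0, G)$values[, 1]
  f0 <- fit_univariate_h2(y0, G, n_restarts = 1, compute_se = FALSE)
  expect_lt(f0$h2, 0.35)
  expect_gt(f0$p_lrt, 0.01)
  # missing rows are dropped together with their GRM rows
  y <- simulate_phenotypes(simulation_scenario(st1, c(sqrt(.5), sqrt(.5)),
                                               300, seed = 19), G)$values[, 1]
  y[1:30] <- NA
  fm <- fit_univariate_h2(y, G, n_restarts = 1, compute_se = FALSE)
  expect_equal(fm$fit$n_individuals, 270)
  expect_true(fm$h2 >= 0 && fm$h2 <= 1)
})
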