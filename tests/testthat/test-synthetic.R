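test_that("genotype simulation is deterministic and validates its inputs", {
  g1 <- simulate_genotypes(20, 50, seed = 3)
  g2 <- simulate_genotypes(20, 50, seed = 3)
  expect_identical(g1$values, g2$values)
  expect_false(identical(g1$values, simulate_genotypes(20, 50, seed = 4)$values))
  expect_error(simulate_genotypes(20, 50, maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulate_genotypes(20, 50, maf_range = c(0.1, 0.6)),
               "maf_range")
  # fixed MAF 0.5: per-marker dosage variance 0.5 in expectation
  g3 <- simulate_genotypes(3000, 40, maf_range = c(0.5, 0.5), seed = 5)
  expect_equal(mean(apply(g3$values, 2, var)), 0.5, tolerance = 0.03)
  # the streamed GRM generator matches compute_grm on the same law
  G1 <- simulate_grm(100, 300, seed = 9)
  expect_equal(dim(G1$values), c(100, 100))
  expect_equal(mean(diag(G1$values)), 1, tolerance = 0.05)
})

test_that("simulated phenotypes follow the implied covariance law", {
  # all E loadings zero and G = I: sample covariance approaches Sigma_A
  st <- make_structure("ip", 2, nA = 1, nE = 1)
  lst <- structure_to_list(st); lst$fixed_specifics$E <- c("trait1", "trait2")
  stA <- structure_from_list(lst)
  thA <- c(0.7, 0.5, 0.3, 0.4, 1e-4, 1e-4)  # tiny E to keep Sigma PD
  scA <- simulation_scenario(stA, thA, 3000, seed = 21)
  YA <- simulate_phenotypes(scA, grm(diag(3000)))$values
  ker <- latentgrm:::sigma_kernels(stA, thA)
  expect_equal(cov(YA), ker$CG + ker$CI, tolerance = 0.05,
               ignore_attr = TRUE)

  # general case: elementwise sample covariance within sampling error
  G <- small_grm(n = 300, m = 2000, seed = 7)
  st2 <- make_structure("ip", 2, nA = 1, nE = 1, rge = TRUE)
  th2 <- c(0.5, 0.45, 0.3, 0.35, 0.55, 0.5, 0.45, 0.5, 0.6)
  reps <- 40
  acc <- matrix(0, 2, 2)
  for (r in 1:reps) {
    sc <- simulation_scenario(st2, th2, 300, seed = 400 + r)
    Yr <- simulate_phenotypes(sc, G)$values
    acc <- acc + cov(Yr)
  }
  ker2 <- latentgrm:::sigma_kernels(st2, latentgrm:::nat_to_raw(st2, th2))
  target <- ker2$CG * mean(G$values[cbind(1:300, 1:300)]) + ker2$CX +
    ker2$CI
  expect_equal(acc / reps, target, tolerance = 0.06, ignore_attr = TRUE)

  # dense and eigen draws realise the same law (same implied covariance)
  sc3 <- simulation_scenario(st2, th2, 60, seed = 31)
  G3 <- grm(small_grm(n = 300, m = 2000, seed = 7)$values[1:60, 1:60])
  Yd <- simulate_phenotypes(sc3, G3, method = "dense")$values
  Ye <- simulate_phenotypes(sc3, G3, method = "eigen")$values
  expect_equal(dim(Yd), dim(Ye))
  S <- implied_sigma(st2, latentgrm:::nat_to_raw(st2, th2), G3$values)
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("missingness masking hits the requested rate", {
  st <- make_structure("cholesky", 3)
  th <- c(0.6, 0.1, 0.5, 0.1, 0.1, 0.55, 0.7, 0.1, 0.6, 0.1, 0.1, 0.65)
  sc <- simulation_scenario(st, th, 1500, missing_rate = 0.18, seed = 41)
  Y <- simulate_phenotypes(sc, grm(diag(1500)))$values
  n_obs <- sum(!is.na(Y))
  expect_equal(n_obs / length(Y), 0.82, tolerance = 0.03)
  expect_error(simulation_scenario(st, th, 100, missing_rate = 1),
               "missing_rate")
})

test_that("the cohort-calibrated scenario is variance-standardised and refittable", {
  sc <- alspac_like_scenario(800, seed = 3)
  expect_equal(sc$missing_rate, 0.18)
  ker <- latentgrm:::sigma_kernels(sc$structure, sc$theta_raw)
  V <- diag(ker$CG) + diag(ker$CI) + 2 * diag(ker$cross_half)
  expect_equal(unname(V), rep(1, 6), tolerance = 1e-8)
  # published rGE signs are built in
  expect_equal(unname(sc$theta_true[c("rGE_cog.cog", "rGE_soc.soc")]),
               c(0.89, -0.62))
  # factorial co-heritability of the headline trait is ~0.99 at truth
  f <- list(structure = sc$structure,
            theta_natural = sc$theta_true, theta_raw = sc$theta_raw,
            se = NULL, vcov_theta = NULL, vcov_raw = NULL, loglik = 0,
            converged = TRUE, optim_ok = TRUE, n_individuals = 800,
            n_observations = 4800, Y = NULL)
  class(f) <- "grmsem_fit"
  fc <- factorial_coheritability(f)
  expect_equal(fc$estimate[fc$quantity == "fc_h2_VIQrev.cog"], 0.99,
               tolerance = 0.01)
})

test_that("positive rGE inflates and negative rGE deflates measured shares", {
  # the sign behaviour of the decomposition at the calibrated truth:
  # measurable (g_related) genetic variance exceeds the pure-A share for
  # the positive-rGE cognitive traits and falls below it for the
  # negative-rGE social traits
  sc <- alspac_like_scenario(800, seed = 3)
  f <- list(structure = sc$structure, theta_natural = sc$theta_true,
            theta_raw = sc$theta_raw, se = NULL, vcov_theta = NULL,
            vcov_raw = NULL, loglik = 0, converged = TRUE, optim_ok = TRUE,
            n_individuals = 800, n_observations = 4800, Y = NULL)
  class(f) <- "grmsem_fit"
  d <- decompose_variance_rge(f)
  cog <- d$trait %in% c("VIQrev", "PIQrev", "LGCrev")
  soc <- d$trait %in% c("SCD", "PP")
  expect_true(all(d$g_related[cog] > d$a_share[cog]))
  expect_true(all(d$twice_cov_share[cog] > 0))
  expect_true(all(d$g_related[soc] < d$a_share[soc]))
  expect_true(all(d$twice_cov_share[soc] < 0))
})
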