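# standardisation and fit statistics operate on fitted-model objects; for
# closed-form checks we build synthetic "fit" objects directly
fake_fit <- function(structure, theta_natural, loglik = 0, n = 1000) {
  cm <- latentgrm:::corr_param_mask(structure)
  theta_raw <- theta_natural
  theta_raw[cm] <- atanh(theta_natural[cm])
  out <- list(structure = structure,
              theta_natural = setNames(theta_natural,
                                       parameter_names(structure)),
              theta_raw = theta_raw, se = NULL, vcov_theta = NULL,
              vcov_raw = NULL, loglik = loglik, converged = TRUE,
              optim_ok = TRUE, n_individuals = n,
              n_observations = n * structure$k,
              Y = NULL)
  class(out) <- "grmsem_fit"
  out
}

test_that("standardised estimates reproduce closed-form cases", {
  st1 <- make_structure("cholesky", 1, trait_names = "t")
  f1 <- fake_fit(st1, c(sqrt(0.5), sqrt(0.5)))
  s1 <- standardize(f1)
  expect_equal(s1$estimate[s1$quantity == "snp_h2_t"], 0.5, tolerance = 1e-12)
  expect_equal(s1$estimate[s1$quantity == "e2_t"], 0.5, tolerance = 1e-12)

  # two traits on one shared A factor, no genetic specifics: rg = 1
  st <- make_structure("ip", 2, nA = 1, nE = 1)
  lst <- structure_to_list(st)
  lst$fixed_specifics$A <- c("trait1", "trait2")
  st <- structure_from_list(lst)
  th <- c(0.5, 0.4, 0.6, 0.55, 0.3, 0.35)
  s <- standardize(fake_fit(st, th))
  expect_equal(s$estimate[s$quantity == "rg_trait1.trait2"], 1,
               tolerance = 1e-10)

  # per trait without rGE: snp_h2 + e2 = 1 after standardisation
  tots <- s$estimate[grepl("^snp_h2_", s$quantity)] +
    s$estimate[grepl("^e2_", s$quantity)]
  expect_equal(tots, rep(1, 2), tolerance = 1e-8)
})

test_that("rg/re match an independent naive correlation computation", {
  set.seed(3)
  st <- make_structure("cholesky", 3)
  th <- rnorm(count_parameters(st), 0.3, 0.2)
  s <- standardize(fake_fit(st, th))
  m <- assemble_matrices(st, th)
  SA <- m$LambdaA %*% t(m$LambdaA)
  SE <- m$LambdaE %*% t(m$LambdaE)
  rgn <- cov2cor(SA); ren <- cov2cor(SE)
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    q <- sprintf("rg_trait%d.trait%d", pair[1], pair[2])
    expect_equal(s$estimate[s$quantity == q], rgn[pair[1], pair[2]],
                 tolerance = 1e-10)
    qe <- sprintf("re_trait%d.trait%d", pair[1], pair[2])
    expect_equal(s$estimate[s$quantity == qe], ren[pair[1], pair[2]],
                 tolerance = 1e-10)
  }
})

test_that("factorial co-heritability follows the squared-loading ratio", {
  st <- make_structure("ip", 1, nA = 1, nE = 1, trait_names = "t")
  # lambdaA = 0.6 common, 0.8 specific: fc = 0.36 / (0.36 + 0.64)
  f <- fake_fit(st, c(0.6, 0.8, 0.5, 0.5))
  fc <- factorial_coheritability(f)
  expect_equal(fc$estimate[fc$quantity == "fc_h2_t.F1"], 0.36,
               tolerance = 1e-12)
  # zero specific: the factor explains everything
  lst <- structure_to_list(st); lst$fixed_specifics$A <- "t"
  f2 <- fake_fit(structure_from_list(lst), c(0.6, 0.5, 0.5))
  fc2 <- factorial_coheritability(f2)
  expect_equal(fc2$estimate[fc2$quantity == "fc_h2_t.F1"], 1,
               tolerance = 1e-12)
  # Cholesky structures have no common factors to attribute to
  expect_error(factorial_coheritability(
    fake_fit(make_structure("cholesky", 1), c(.5, .5))), "IP-family")
})

test_that("rGE-aware variance decomposition gives signed, consistent shares", {
  stt <- make_structure("ip", 1, nA = 1, nE = 1, rge = TRUE,
                        trait_names = "t")
  stt$A$specific_free[1] <- FALSE
  stt$E$specific_free[1] <- FALSE
  f <- fake_fit(stt, c(0.6, 0.8, 0.5))
  d <- decompose_variance_rge(f)
  expect_equal(d$a_share, 0.36 / 1.48, tolerance = 1e-10)
  expect_equal(d$e_share, 0.64 / 1.48, tolerance = 1e-10)
  expect_equal(d$twice_cov_share, 0.48 / 1.48, tolerance = 1e-10)
  expect_equal(d$a_share + d$e_share + d$twice_cov_share, 1,
               tolerance = 1e-8)
  expect_equal(d$g_related + d$e_related, 1, tolerance = 1e-8)

  # negative rGE: negative cov share, g_related below the pure-A share
  fneg <- fake_fit(stt, c(0.6, 0.8, -0.62))
  dn <- decompose_variance_rge(fneg)
  expect_lt(dn$twice_cov_share, 0)
  expect_lt(dn$g_related, dn$a_share)

  # rGE = 0 reduces to the independence decomposition
  f0 <- fake_fit(stt, c(0.6, 0.8, 0))
  d0 <- decompose_variance_rge(f0)
  expect_equal(d0$twice_cov_share, 0, tolerance = 1e-12)
  expect_equal(d0$g_related, d0$a_share, tolerance = 1e-12)
})

test_that("information criteria match the reported-arithmetic conventions", {
  expect_equal(aic_from_ll(-13406.46, 28), 26868.92, tolerance = 1e-9)
  expect_equal(bic_from_ll(-9818.95, 43, 4412), 19998.76, tolerance = 0.05)
  expect_equal(aic_from_ll(0, 0), 0)
})

test_that("likelihood-ratio tests reproduce reported comparisons", {
  t1 <- lrt(list(loglik = -13402.94, n_params = 34),
            list(loglik = -13397.26, n_params = 42))
  expect_lt(abs(t1$chi2 - 11.36), 0.005)
  expect_equal(t1$ddf, 8)
  expect_lt(abs(t1$p - 0.18), 0.005)  # reported to two decimals

  t2 <- lrt(list(loglik = -13404.18, n_params = 28),
            list(loglik = -13397.26, n_params = 42))
  expect_lt(abs(t2$chi2 - 13.84), 0.005)
  expect_equal(t2$ddf, 14)
  expect_lt(abs(t2$p - 0.46), 0.005)

  t0 <- lrt(list(loglik = -5, n_params = 3), list(loglik = -5, n_params = 3))
  expect_equal(t0$chi2, 0)
  expect_equal(t0$p, 1)
  expect_error(lrt(list(loglik = -5, n_params = 5),
                   list(loglik = -5, n_params = 3)), "more parameters")
  expect_error(lrt(list(loglik = -4, n_params = 3),
                   list(loglik = -5, n_params = 5)), "negative")
})

test_that("SRMR follows the diagonal-inclusive triangle convention", {
  S <- matrix(c(1, 0.3, 0.3, 1), 2)
  expect_equal(latentgrm:::srmr_matrices(S, S), 0)
  Sig <- matrix(c(1, 0.4, 0.4, 1), 2)  # one correlation off by 0.1
  expect_equal(latentgrm:::srmr_matrices(S, Sig), sqrt(0.01 / 3),
               tolerance = 1e-12)
})

test_that("rGE evidence verdict needs both fit improvement and precise estimates", {
  st_ip <- make_structure("ip", 2, nA = 1, nE = 1)
  st_rge <- make_structure("ip", 2, nA = 1, nE = 1, rge = TRUE)
  th <- c(0.5, 0.4, 0.3, 0.35, 0.6, 0.55, 0.4, 0.45)
  f0 <- fake_fit(st_ip, th, loglik = -1000)
  # identical fit: not supported
  f_same <- fake_fit(st_rge, c(th, 0), loglik = -1000)
  f_same$se <- setNames(rep(0.1, 9), parameter_names(st_rge))
  expect_false(rge_evidence(f0, f_same)$supported)
  # big improvement but imprecise rGE (0.3 +- 0.4): still not supported
  f_wide <- fake_fit(st_rge, c(th, 0.3), loglik = -990)
  f_wide$se <- setNames(c(rep(0.1, 8), 0.4), parameter_names(st_rge))
  ev <- rge_evidence(f0, f_wide)
  expect_true(ev$aic_improves)
  expect_false(ev$supported)
  # improvement + tight interval: supported
  f_good <- fake_fit(st_rge, c(th, 0.6), loglik = -990)
  f_good$se <- setNames(c(rep(0.1, 8), 0.15), parameter_names(st_rge))
  expect_true(rge_evidence(f0, f_good)$supported)
})

test_that("model comparison table carries exact AIC/BIC identities", {
  fits <- list(base = list(loglik = -100, n_params = 6, n_individuals = 50),
               nested = list(loglik = -103, n_params = 3,
                             n_individuals = 50))
  tab <- fit_comparison(fits, baseline = "base")
  expect_equal(tab$aic, -2 * tab$loglik + 2 * tab$n_params)
  expect_equal(tab$bic, -2 * tab$loglik + tab$n_params * log(50))
  expect_equal(tab$lrt_chi2[2], 6)
  expect_equal(tab$ddf[2], 3)
})

test_that("delta-method heritability SEs match a parametric bootstrap", {
  G <- small_grm(n = 400, m = 2000, seed = 7)
  st1 <- make_structure("cholesky", 1)
  sc <- simulation_scenario(st1, c(sqrt(.5), sqrt(.5)), 400, seed = 55)
  y <- simulate_phenotypes(sc, G)$values[, 1]
  f <- fit_univariate_h2(y, G, n_restarts = 1)
  h2b <- numeric(200)
  for (b in 1:200) {
    scb <- simulation_scenario(st1, unname(f$fit$theta_natural), 400,
                               seed = 7000 + b)
    yb <- simulate_phenotypes(scb, G)$values[, 1]
    h2b[b] <- fit_univariate_h2(yb, G, n_restarts = 1, compute_se = FALSE,
                                optim_factr = 1e7, tol = 0.05)$h2
  }
  expect_lt(abs(f$se / sd(h2b) - 1), 0.10)
})
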