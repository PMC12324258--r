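# Synthetic data -------------------------------------------------------------

#' Simulate unrelated-individual genotypes
#'
#' Per-marker minor-allele frequencies are drawn uniformly from `maf_range`
#' and dosages are Binomial(2, p), i.i.d. across individuals (unrelated by
#' construction). Deterministic given `seed`.
#'
#' @param n individuals (>= 2).
#' @param m markers (>= 1).
#' @param maf_range length-2 range within (0, 0.5].
#' @param seed integer seed.
#' @return A [genotype_matrix()].
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), seed = 1) {
  stopifnot(n >= 2, m >= 1)
  if (min(maf_range) <= 0 || max(maf_range) > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  p <- runif(m, maf_range[1], maf_range[2])
  X <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n, ncol = m)
  genotype_matrix(X, individual_ids = paste0("ind", seq_len(n)),
                  marker_ids = paste0("snp", seq_len(m)))
}

#' Simulate a GRM directly (marker-streamed)
#'
#' Equivalent to `compute_grm(simulate_genotypes(n, m, ...))` for complete
#' data, but accumulates the standardised crossproduct in marker blocks so
#' marker counts in the tens of thousands (the regime matching cohort-scale
#' GREML standard errors) stay within desk memory.
#'
#' @inheritParams simulate_genotypes
#' @param block_size markers per block.
#' @return A [grm()].
#' @export
simulate_grm <- function(n, m, maf_range = c(0.05, 0.5), seed = 1,
                         block_size = 5000L) {
  stopifnot(n >= 2, m >= 1)
  if (min(maf_range) <= 0 || max(maf_range) > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  acc <- matrix(0, n, n)
  used <- 0L
  left <- m
  while (left > 0L) {
    b <- min(block_size, left)
    p <- runif(b, maf_range[1], maf_range[2])
    # Binomial(2, p) as the sum of two Bernoulli draws (fast at this scale)
    pmat <- rep(p, each = n)
    X <- matrix((runif(n * b) < pmat) + (runif(n * b) < pmat),
                nrow = n, ncol = b)
    phat <- colMeans(X) / 2
    ok <- phat > 0 & phat < 1
    if (any(ok)) {
      Z <- sweep(X[, ok, drop = FALSE], 2L, 2 * phat[ok], "-")
      Z <- sweep(Z, 2L, sqrt(2 * phat[ok] * (1 - phat[ok])), "/")
      acc <- acc + tcrossprod(Z)
      used <- used + sum(ok)
    }
    left <- left - b
  }
  if (used == 0L) stop("no polymorphic markers simulated")
  grm(acc / used, individual_ids = paste0("ind", seq_len(n)),
      n_markers_per_pair = matrix(used, n, n))
}

#' Define a simulation scenario
#'
#' Bundles a model structure, its true parameter values and the sampling
#' conditions (sample size, marker count, missingness) for phenotype
#' generation.
#'
#' @param structure a [make_structure()] object.
#' @param theta_true true parameter vector (natural scale; correlation-type
#'   entries in (-1, 1)).
#' @param n_individuals,n_markers sample dimensions.
#' @param maf_range marker MAF range.
#' @param missing_rate scalar or per-trait missing-completely-at-random
#'   rate in [0, 1).
#' @param seed integer seed.
#' @return Object of class `"simulation_scenario"`.
#' @export
simulation_scenario <- function(structure, theta_true, n_individuals,
                                n_markers = 5000, maf_range = c(0.05, 0.5),
                                missing_rate = 0, seed = 1) {
  stopifnot(inherits(structure, "grmsem_structure"))
  if (length(theta_true) != count_parameters(structure))
    stop("theta_true has the wrong length")
  if (any(missing_rate < 0 | missing_rate >= 1))
    stop("missing_rate must lie in [0, 1)")
  cm <- corr_param_mask(structure)
  theta_raw <- theta_true
  theta_raw[cm] <- atanh(theta_true[cm])
  out <- list(structure = structure,
              theta_true = setNames(theta_true, parameter_names(structure)),
              theta_raw = theta_raw,
              n_individuals = as.integer(n_individuals),
              n_markers = as.integer(n_markers), maf_range = maf_range,
              missing_rate = missing_rate, seed = as.integer(seed))
  class(out) <- "simulation_scenario"
  out
}

#' @export
print.simulation_scenario <- function(x, ...) {
  cat(sprintf("simulation_scenario: %s, k=%d, n=%d, m=%d markers, missing %s\n",
              x$structure$kind, x$structure$k, x$n_individuals, x$n_markers,
              paste(signif(x$missing_rate, 3), collapse = "/")))
  invisible(x)
}

#' Simulate phenotypes from a scenario
#'
#' Draws one mean-zero Gaussian n x k phenotype matrix from the model law
#' implied by the scenario's structure and true parameters, given a GRM.
#' `method = "eigen"` (default) draws row-wise in the eigenbasis of G, where
#' rows are independent with covariance `C_G d_i + C_X sqrt(d_i) + C_I`;
#' `method = "dense"` draws through a matrix square root of the full
#' nk x nk implied covariance. Both sample exactly the same law; the dense
#' route costs O((nk)^3) and is intended for small validation runs.
#' Entries are then masked missing-completely-at-random at the scenario's
#' per-trait rate. Deterministic given the scenario seed.
#'
#' @param scenario a [simulation_scenario()].
#' @param G a [grm()] or n x n relatedness matrix (positive semi-definite).
#' @param method `"eigen"` or `"dense"`.
#' @return A `phenotype_table` with the simulated values.
#' @export
simulate_phenotypes <- function(scenario, G, method = c("eigen", "dense")) {
  method <- match.arg(method)
  stopifnot(inherits(scenario, "simulation_scenario"))
  if (!inherits(G, "grm")) G <- grm(as.matrix(G))
  n <- nrow(G$values)
  if (n != scenario$n_individuals)
    stop("GRM size does not match the scenario")
  k <- scenario$structure$k
  set.seed(scenario$seed %% .Machine$integer.max)
  if (method == "eigen") {
    G <- grm_eigen(G)
    ker <- sigma_kernels(scenario$structure, scenario$theta_raw)
    Z <- matrix(rnorm(n * k), n, k)
    Ytil <- sim_eigen_cpp(Z, pmax(G$eigen$values, 0), ker$CG, ker$CX,
                          ker$CI)
    Y <- G$eigen$vectors %*% Ytil
  } else {
    S <- implied_sigma(scenario$structure, scenario$theta_raw, G$values)
    ed <- eigen(S, symmetric = TRUE)
    if (min(ed$values) < -1e-8 * max(ed$values))
      stop("implied covariance not positive semi-definite: invalid scenario")
    y <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * rnorm(n * k))
    Y <- matrix(y, n, k)
  }
  rate <- rep(scenario$missing_rate, length.out = k)
  for (j in seq_len(k))
    if (rate[j] > 0) Y[runif(n) < rate[j], j] <- NA_real_
  tn <- scenario$structure$trait_names
  dimnames(Y) <- list(G$individual_ids, tn)
  out <- list(values = Y, trait_labels = tn,
              individual_ids = G$individual_ids,
              transform_log = sprintf("simulated (seed %d, method %s)",
                                      scenario$seed, method))
  class(out) <- "phenotype_table"
  out
}

#' Six-trait cohort-calibrated simulation scenario
#'
#' A 6-trait IP(2,2) scenario with gene-environment correlation, emulating
#' the statistical structure of a mid-childhood cognition/language/social
#' battery: a cognitive/language domain (reverse-coded verbal IQ,
#' performance IQ, listening comprehension, plus a pragmatic-composite
#' cross-loading) and a social-difficulties domain (social communication
#' difficulties, peer problems, pragmatic composite), with positive rGE
#' (+0.89) in the cognitive pair and negative rGE (-0.62) in the social
#' pair. Common-factor loadings use the published point estimates where
#' available; the remaining loadings are round plausible values, marked
#' `assumed` in the returned annotation. Specific residual loadings are
#' solved so every trait's total implied variance is exactly 1.
#'
#' @param n number of individuals (>= 500).
#' @param seed integer seed.
#' @param missing_rate per-entry missing-completely-at-random rate; the
#'   default 0.18 matches the cohort regime (observed entries about 82% of
#'   n x k). Set 0 for complete-data experiments.
#' @param n_markers markers for the companion GRM.
#' @return A [simulation_scenario()] with an extra `loading_sources`
#'   annotation.
#' @export
alspac_like_scenario <- function(n, seed = 1, missing_rate = 0.18,
                                 n_markers = 5000) {
  stopifnot(n >= 500)
  tn <- c("VIQrev", "PIQrev", "LGCrev", "SCD", "PRCrev", "PP")
  pattern <- list(cog = c("VIQrev", "PIQrev", "LGCrev", "PRCrev"),
                  soc = c("SCD", "PP", "PRCrev"))
  pattern_E <- list(cog = c("VIQrev", "PIQrev", "LGCrev"),
                    soc = c("SCD", "PP", "PRCrev"))
  st <- make_structure("ip", k = 6, nA = 2, nE = 2,
                       pattern_A = pattern, pattern_E = pattern_E,
                       trait_names = tn, rge = TRUE)
  # published point estimates where printed; remaining values assumed
  lamA <- list(cog = c(VIQrev = 0.45, PIQrev = 0.40, LGCrev = 0.38,
                       PRCrev = 0.34),
               soc = c(SCD = 0.39, PP = 0.37, PRCrev = 0.28))
  lamE <- list(cog = c(VIQrev = 0.57, PIQrev = 0.50, LGCrev = 0.45),
               soc = c(SCD = 0.45, PP = 0.55, PRCrev = 0.82))
  lamAS <- c(VIQrev = 0.045, PIQrev = 0.20, LGCrev = 0.04, SCD = 0.144,
             PRCrev = 0.10, PP = 0.123)
  rge <- c(cog = 0.89, soc = -0.62)
  sources <- c("0.45, 0.40, 0.38, 0.34, 0.39, 0.37, 0.28 (A loadings), 0.57, 0.82 (E loadings), +0.89, -0.62 (rGE): published estimates",
               "remaining E loadings and specific loadings: assumed, chosen so factorial co-heritabilities match the published values and each trait variance is 1")
  k <- 6
  LA <- matrix(0, k, 2 + k, dimnames = list(tn, NULL))
  LE <- matrix(0, k, 2 + k, dimnames = list(tn, NULL))
  for (f in 1:2) {
    LA[names(lamA[[f]]), f] <- lamA[[f]]
    LE[names(lamE[[f]]), f] <- lamE[[f]]
  }
  LA[cbind(1:k, 2 + 1:k)] <- lamAS[tn]
  # per-trait implied variances so far
  a_common <- rowSums(LA[, 1:2]^2)
  a <- a_common + lamAS[tn]^2
  cj <- LA[, 1] * LE[, 1] * rge["cog"] + LA[, 2] * LE[, 2] * rge["soc"]
  e_target <- 1 - a - 2 * cj
  e_common <- rowSums(LE[, 1:2]^2)
  if (any(e_target - e_common <= 0))
    stop("inconsistent preset: negative specific residual variance")
  LE[cbind(1:k, 2 + 1:k)] <- sqrt(e_target - e_common)
  Phicov <- matrix(0, 2 + k, 2 + k)
  Phicov[1, 1] <- rge["cog"]; Phicov[2, 2] <- rge["soc"]
  mats <- list(LambdaA = LA, LambdaE = LE, PhiA = diag(2 + k),
               PhiE = diag(2 + k), Phicov = Phicov)
  theta_raw <- flatten_matrices(st, mats)
  theta_nat <- theta_raw
  cm <- corr_param_mask(st)
  theta_nat[cm] <- tanh(theta_raw[cm])
  sc <- simulation_scenario(st, theta_nat, n_individuals = n,
                            n_markers = n_markers,
                            missing_rate = missing_rate, seed = seed)
  sc$loading_sources <- sources
  sc
}
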