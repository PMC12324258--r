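# Phenotypic confirmatory factor analysis -----------------------------------
#
# Compact ML confirmatory factor fitter on a sample covariance matrix, used
# by the split-half phenotypic stage: Sigma = Lambda Phi Lambda' + diag(psi)
# with a fixed loading pattern, unit factor variances, optional free factor
# correlations, and log-parameterised uniquenesses. The discrepancy is the
# Wishart ML fit function F = log|Sigma| + tr(S Sigma^-1) - log|S| - k.

#' Fit a confirmatory factor model by maximum likelihood
#'
#' @param S k x k sample covariance (or correlation) matrix.
#' @param n number of observations behind `S`.
#' @param pattern list, one element per factor, of trait indices or names
#'   (column names of `S`) loading on it.
#' @param correlated logical: free the factor correlations.
#' @return Object of class `"cfa_fit"` with loadings, uniquenesses, factor
#'   correlations, `loglik`, `n_params`, `chi2`, `df`, baseline statistics
#'   and the implied covariance.
#' @export
fit_cfa <- function(S, n, pattern, correlated = TRUE) {
  S <- as.matrix(S)
  k <- nrow(S)
  tn <- colnames(S) %||% paste0("trait", seq_len(k))
  pattern <- lapply(pattern, function(ix)
    if (is.character(ix)) match(ix, tn) else as.integer(ix))
  p <- length(pattern)
  mask <- matrix(FALSE, k, p)
  for (f in seq_len(p)) mask[pattern[[f]], f] <- TRUE
  nload <- sum(mask)
  ncorr <- if (correlated && p > 1) p * (p - 1) / 2 else 0
  npar <- nload + k + ncorr
  logdetS <- determinant(S, logarithm = TRUE)$modulus[1]

  build <- function(th) {
    L <- matrix(0, k, p)
    L[mask] <- th[seq_len(nload)]
    psi <- exp(th[nload + seq_len(k)])
    Phi <- diag(p)
    if (ncorr > 0) {
      Phi[upper.tri(Phi)] <- tanh(th[nload + k + seq_len(ncorr)])
      Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
    }
    L %*% Phi %*% t(L) + diag(psi, k)
  }
  discrep <- function(th) {
    Sig <- build(th)
    R <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(R)) return(1e10)
    logdet <- 2 * sum(log(diag(R)))
    logdet + sum(diag(chol2inv(R) %*% S)) - logdetS - k
  }
  start <- c(sqrt(diag(S))[row(mask)[mask]] * 0.7,
             log(diag(S) * 0.5), rep(0, ncorr))
  opt <- optim(start, discrep, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  Fmin <- opt$value
  Sig <- build(opt$par)
  chi2 <- max(0, (n - 1) * Fmin)
  df <- k * (k + 1) / 2 - npar
  # independence baseline
  Fb <- -determinant(cov2cor(S), logarithm = TRUE)$modulus[1]
  chi2_b <- max(0, (n - 1) * Fb)
  df_b <- k * (k - 1) / 2
  loglik <- -n / 2 * (k * log(2 * pi) +
                        determinant(Sig, logarithm = TRUE)$modulus[1] +
                        sum(diag(solve(Sig, S))))
  L <- matrix(0, k, p, dimnames = list(tn, names(pattern) %||%
                                         paste0("P", seq_len(p))))
  L[mask] <- opt$par[seq_len(nload)]
  Phi <- diag(p)
  if (ncorr > 0) {
    Phi[upper.tri(Phi)] <- tanh(opt$par[nload + k + seq_len(ncorr)])
    Phi[lower.tri(Phi)] <- t(Phi)[lower.tri(Phi)]
  }
  # canonical sign: largest loading per factor positive
  for (f in seq_len(p)) {
    idx <- which(mask[, f])
    if (length(idx) && L[idx[which.max(abs(L[idx, f]))], f] < 0) {
      L[, f] <- -L[, f]
      Phi[f, -f] <- -Phi[f, -f]; Phi[-f, f] <- -Phi[-f, f]
    }
  }
  out <- list(loadings = L, uniquenesses = exp(opt$par[nload + seq_len(k)]),
              factor_corr = Phi, implied = Sig, sample_cov = S, n = n,
              loglik = loglik, n_params = npar, n_individuals = n,
              chi2 = chi2, df = df, chi2_baseline = chi2_b,
              df_baseline = df_b, Fmin = Fmin,
              converged = opt$convergence == 0)
  class(out) <- "cfa_fit"
  out
}

#' @export
print.cfa_fit <- function(x, ...) {
  cat(sprintf("cfa_fit: %d traits, %d factor(s), %d parameters; chi2(%d) = %.2f\n",
              nrow(x$loadings), ncol(x$loadings), x$n_params, x$df, x$chi2))
  print(round(x$loadings, 3))
  if (ncol(x$loadings) > 1)
    cat("factor correlations:",
        round(x$factor_corr[upper.tri(x$factor_corr)], 3), "\n")
  invisible(x)
}

#' Incremental and absolute fit indices for a phenotypic factor model
#'
#' CFI, TLI, RMSEA and SRMR from the ML chi-square of a [fit_cfa()] model
#' against its independence baseline (the conventional thresholds in this
#' literature are CFI/TLI >= 0.95, RMSEA <= 0.06, SRMR <= 0.08).
#'
#' @param cfa_fit a [fit_cfa()] object.
#' @return List with `cfi`, `tli`, `rmsea`, `srmr`, `chi2`, `df`.
#' @export
phenotypic_fit_indices <- function(cfa_fit) {
  stopifnot(inherits(cfa_fit, "cfa_fit"))
  if (cfa_fit$df_baseline <= 0) stop("baseline df = 0: indices undefined")
  t1 <- max(cfa_fit$chi2 - cfa_fit$df, 0)
  tb <- max(cfa_fit$chi2_baseline - cfa_fit$df_baseline, t1)
  cfi <- if (tb == 0) 1 else 1 - t1 / tb
  rb <- cfa_fit$chi2_baseline / cfa_fit$df_baseline
  rm_ <- if (cfa_fit$df > 0) cfa_fit$chi2 / cfa_fit$df else 0
  tli <- if (rb == 1) 1 else (rb - rm_) / (rb - 1)
  rmsea <- if (cfa_fit$df > 0)
    sqrt(max(cfa_fit$chi2 - cfa_fit$df, 0) / (cfa_fit$df * (cfa_fit$n - 1)))
  else 0
  list(cfi = cfi, tli = min(tli, 1), rmsea = rmsea,
       srmr = srmr_matrices(cfa_fit$sample_cov, cfa_fit$implied),
       chi2 = cfa_fit$chi2, df = cfa_fit$df)
}
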