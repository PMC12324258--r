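# Standardised summaries and fit statistics ---------------------------------

# all standardised quantities as one named vector of theta (raw scale),
# so delta-method SEs can be taken numerically in one pass
std_quantities <- function(structure, theta_raw) {
  ker <- sigma_kernels(structure, theta_raw)
  k <- structure$k
  tn <- structure$trait_names
  a <- diag(ker$CG); e <- diag(ker$CI); cc <- diag(ker$cross_half)
  V <- a + e + 2 * cc
  if (any(V <= 0)) stop("invalid fit: non-positive implied trait variance")
  out <- c(setNames(a / V, paste0("snp_h2_", tn)),
           setNames(e / V, paste0("e2_", tn)),
           setNames(2 * cc / V, paste0("twice_cov_share_", tn)),
           setNames((a + cc) / V, paste0("g_related_", tn)),
           setNames((e + cc) / V, paste0("e_related_", tn)))
  if (k > 1) {
    sdA <- sqrt(pmax(a, 0)); sdE <- sqrt(pmax(e, 0))
    pair <- which(upper.tri(ker$CG), arr.ind = TRUE)
    rg <- ker$CG[upper.tri(ker$CG)] / (sdA[pair[, 1]] * sdA[pair[, 2]])
    re <- ker$CI[upper.tri(ker$CI)] / (sdE[pair[, 1]] * sdE[pair[, 2]])
    pn <- paste0(tn[pair[, 1]], ".", tn[pair[, 2]])
    out <- c(out, setNames(rg, paste0("rg_", pn)),
             setNames(re, paste0("re_", pn)))
  }
  mats <- assemble_matrices(structure, theta_raw)
  lam_std <- function(side, L, part) {
    v <- numeric(0)
    for (f in seq_len(side$n_common)) {
      idx <- which(side$common_free[, f])
      v <- c(v, setNames(L[idx, f] / sqrt(V[idx]),
                         sprintf("lambda%s_%s.%s", part, tn[idx],
                                 side$factor_names[f])))
    }
    if (!is.null(side$specific_free)) {
      idx <- which(side$specific_free)
      v <- c(v, setNames(L[cbind(idx, side$n_common + idx)] / sqrt(V[idx]),
                         sprintf("lambda%sS_%s", part, tn[idx])))
    }
    v
  }
  out <- c(out, lam_std(structure$A, mats$LambdaA, "A"),
           lam_std(structure$E, mats$LambdaE, "E"))
  # factorial co-heritability / co-environmentality (IP-family parts only)
  fc_part <- function(side, L, denom, label) {
    v <- numeric(0)
    if (side$type == "chol") return(v)
    for (f in seq_len(side$n_common)) {
      idx <- which(side$common_free[, f])
      v <- c(v, setNames(L[idx, f]^2 / denom[idx],
                         sprintf("%s_%s.%s", label, tn[idx],
                                 side$factor_names[f])))
    }
    v
  }
  c(out, fc_part(structure$A, mats$LambdaA, a, "fc_h2"),
    fc_part(structure$E, mats$LambdaE, e, "fc_e2"))
}

#' Standardised estimates from a fitted GRM-SEM model
#'
#' Per-trait SNP heritability and residual share, pairwise genetic and
#' residual correlations, standardised factor loadings, factorial
#' co-heritability / co-environmentality, and (with rGE) the signed
#' variance shares. Trait variance is the model-implied
#' \eqn{V_j = a_j + e_j + 2c_j} with
#' \eqn{a_j = [\Lambda_A \Phi_A \Lambda_A']_{jj}},
#' \eqn{e_j = [\Lambda_E \Phi_E \Lambda_E']_{jj}} and
#' \eqn{c_j = [\Lambda_A \Phi_{cov}' \Lambda_E']_{jj}}. Standard errors are
#' delta-method (numerical Jacobian against the observed-information
#' covariance of the raw parameters).
#'
#' @param fit a converged [grmsem_fit()].
#' @return Object of class `"grmsem_std"`: a data frame with columns
#'   `quantity`, `estimate`, `se`.
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "grmsem_fit"))
  est <- std_quantities(fit$structure, fit$theta_raw)
  se <- rep(NA_real_, length(est))
  if (!is.null(fit$vcov_raw) && all(is.finite(fit$vcov_raw))) {
    J <- matrix(0, length(est), length(fit$theta_raw))
    for (i in seq_along(fit$theta_raw)) {
      h <- 1e-5 * max(1, abs(fit$theta_raw[i]))
      tp <- tm <- fit$theta_raw
      tp[i] <- tp[i] + h; tm[i] <- tm[i] - h
      J[, i] <- (std_quantities(fit$structure, tp) -
                   std_quantities(fit$structure, tm)) / (2 * h)
    }
    se <- sqrt(pmax(rowSums((J %*% fit$vcov_raw) * J), 0))
  }
  out <- data.frame(quantity = names(est), estimate = unname(est),
                    se = se, stringsAsFactors = FALSE)
  class(out) <- c("grmsem_std", "data.frame")
  out
}

#' Factorial co-heritability and co-environmentality
#'
#' The proportion of a trait's genetic variance explained by one latent
#' genetic factor, \eqn{fc_{h2,jf} = \lambda_{A,jf}^2 / a_j}, and the
#' residual analogue \eqn{fc_{e2,jf} = \lambda_{E,jf}^2 / e_j}. The
#' denominators are the pure-A and pure-E trait variances (the Cov(A,E)
#' term is excluded, keeping each fc a proportion of its own side's
#' variance). Requires an IP-family part (common factors plus specifics).
#'
#' @param fit a converged [grmsem_fit()].
#' @return Data frame with columns `quantity` (fc_h2_trait.factor /
#'   fc_e2_trait.factor), `estimate`, `se`.
#' @export
factorial_coheritability <- function(fit) {
  std <- standardize(fit)
  out <- std[grepl("^fc_", std$quantity), , drop = FALSE]
  if (nrow(out) == 0)
    stop("no common factors: factorial co-heritability needs an IP-family part")
  rownames(out) <- NULL
  out
}

#' rGE-aware variance decomposition
#'
#' Signed per-trait shares of the model-implied variance: `a_share`
#' (\eqn{a_j/V_j}), `e_share` (\eqn{e_j/V_j}) and `twice_cov_share`
#' (\eqn{2c_j/V_j}, which is negative under negative rGE), plus the
#' combined `g_related` (\eqn{(a_j+c_j)/V_j}) and `e_related`
#' (\eqn{(e_j+c_j)/V_j}) contributions; the triple sums to 1 and
#' `g_related + e_related = 1`.
#'
#' @param fit a fitted rGE-enabled model ([grmsem_fit()]); also valid for
#'   independence models, where the cov shares are 0.
#' @return Data frame, one row per trait.
#' @export
decompose_variance_rge <- function(fit) {
  std <- standardize(fit)
  tn <- fit$structure$trait_names
  pick <- function(prefix) {
    v <- std[match(paste0(prefix, "_", tn), std$quantity), ]
    setNames(v$estimate, tn)
  }
  data.frame(trait = tn,
             a_share = unname(pick("snp_h2")),
             e_share = unname(pick("e2")),
             twice_cov_share = unname(pick("twice_cov_share")),
             g_related = unname(pick("g_related")),
             e_related = unname(pick("e_related")),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Information criteria from a log-likelihood
#'
#' `aic_from_ll` returns \eqn{-2 LL + 2 N_p}; `bic_from_ll` returns
#' \eqn{-2 LL + N_p \ln N}, with N the number of individuals.
#'
#' @param ll log-likelihood.
#' @param n_params free parameter count.
#' @param n_individuals sample size (individuals).
#' @return Numeric scalar.
#' @export
aic_from_ll <- function(ll, n_params) -2 * ll + 2 * n_params

#' @rdname aic_from_ll
#' @export
bic_from_ll <- function(ll, n_params, n_individuals)
  -2 * ll + n_params * log(n_individuals)

as_fit_info <- function(x) {
  if (inherits(x, "grmsem_fit"))
    list(loglik = x$loglik, n_params = count_parameters(x$structure),
         n_individuals = x$n_individuals)
  else list(loglik = x$loglik, n_params = x$n_params,
            n_individuals = x$n_individuals %||% NA_real_)
}

#' Likelihood-ratio test between nested fits
#'
#' \eqn{\chi^2 = 2(LL_{full} - LL_{nested})}, degrees of freedom the
#' difference in free-parameter counts, p-value from the upper chi-square
#' tail. Accepts [grmsem_fit()] objects or plain lists with `loglik` and
#' `n_params` (so fit tables can be recomputed from reported statistics).
#'
#' @param fit_nested,fit_full the two models (nested has fewer or equal
#'   parameters).
#' @param tol tolerance on a slightly negative chi-square from numerical
#'   optimisation noise.
#' @return List with `chi2`, `ddf`, `p`.
#' @export
lrt <- function(fit_nested, fit_full, tol = 1e-6) {
  a <- as_fit_info(fit_nested); b <- as_fit_info(fit_full)
  if (a$n_params > b$n_params)
    stop("nested model has more parameters than the full model")
  chi2 <- 2 * (b$loglik - a$loglik)
  if (chi2 < -tol)
    stop("negative LRT chi-square (", format(chi2),
         "): models not nested or not converged")
  chi2 <- max(0, chi2)
  ddf <- b$n_params - a$n_params
  p <- if (ddf == 0) as.numeric(chi2 <= tol) else
    pchisq(chi2, df = ddf, lower.tail = FALSE)
  list(chi2 = chi2, ddf = ddf, p = p)
}

#' Standardised root mean square residual
#'
#' Discrepancy between the model-implied total phenotypic correlation
#' structure (the per-individual k x k block of the implied covariance,
#' with unit GRM diagonal: \eqn{C_G + C_X + C_I}) and the sample
#' correlation structure, using sample-standardised residuals over the
#' lower triangle including the diagonal (Hu-Bentler convention):
#' \eqn{\sqrt{\mathrm{mean}\,[(s_{ij} - \sigma_{ij})/(s_i s_j)]^2}}.
#'
#' @param fit a [grmsem_fit()].
#' @param sample_cov optional k x k sample covariance; defaults to the
#'   pairwise-complete covariance of the fitted phenotypes.
#' @return SRMR (non-negative scalar).
#' @export
srmr <- function(fit, sample_cov = NULL) {
  stopifnot(inherits(fit, "grmsem_fit"))
  if (is.null(sample_cov))
    sample_cov <- cov(fit$Y, use = "pairwise.complete.obs")
  S <- as.matrix(sample_cov)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    warning("sample covariance not positive definite; proceeding on correlations")
  ker <- sigma_kernels(fit$structure, fit$theta_raw)
  Sig <- ker$CG + ker$CX + ker$CI
  srmr_matrices(S, Sig)
}

srmr_matrices <- function(S, Sigma) {
  s <- sqrt(diag(S))
  R <- (S - Sigma) / tcrossprod(s)
  tri <- lower.tri(R, diag = TRUE)
  sqrt(mean(R[tri]^2))
}

#' Model comparison table
#'
#' Side-by-side fit statistics for several models, with likelihood-ratio
#' tests against a baseline (by convention the saturated Cholesky model,
#' given first).
#'
#' @param fits named list of [grmsem_fit()] objects (or plain lists with
#'   `loglik`, `n_params`, `n_individuals`).
#' @param baseline name or index of the baseline model (default 1).
#' @param sample_cov optional shared sample covariance for SRMR.
#' @return Data frame with columns `model`, `n_params`, `loglik`, `aic`,
#'   `bic`, `srmr`, `ddf`, `lrt_chi2`, `lrt_p`.
#' @export
fit_comparison <- function(fits, baseline = 1, sample_cov = NULL) {
  nm <- names(fits) %||% paste0("model", seq_along(fits))
  base_idx <- if (is.character(baseline)) match(baseline, nm) else baseline
  base_info <- as_fit_info(fits[[base_idx]])
  rows <- lapply(seq_along(fits), function(i) {
    info <- as_fit_info(fits[[i]])
    is_base <- i == base_idx
    sr <- if (inherits(fits[[i]], "grmsem_fit"))
      srmr(fits[[i]], sample_cov) else NA_real_
    if (!is_base && info$n_params <= base_info$n_params) {
      tst <- lrt(info, base_info)
    } else tst <- list(chi2 = NA_real_, ddf = NA_integer_, p = NA_real_)
    data.frame(model = nm[i], n_params = info$n_params,
               loglik = info$loglik,
               aic = aic_from_ll(info$loglik, info$n_params),
               bic = bic_from_ll(info$loglik, info$n_params,
                                 info$n_individuals),
               srmr = sr, ddf = tst$ddf, lrt_chi2 = tst$chi2,
               lrt_p = tst$p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Evidence verdict for gene-environment correlation
#'
#' rGE is supported when the rGE model fits better than the independence
#' model (AIC improves or LRT p < 0.05) AND every estimated rGE parameter's
#' Wald interval excludes zero. Components are reported separately.
#'
#' @param ip_fit the independence IP fit (nested).
#' @param ip_rge_fit the rGE-extended fit.
#' @param level Wald confidence level.
#' @return List with `supported`, `aic_improves`, `lrt`, and a data frame
#'   `rge` of estimates, SEs, Wald z and p.
#' @export
rge_evidence <- function(ip_fit, ip_rge_fit, level = 0.95) {
  tst <- lrt(ip_fit, ip_rge_fit)
  aic_improves <-
    aic_from_ll(ip_rge_fit$loglik, count_parameters(ip_rge_fit$structure)) <
    aic_from_ll(ip_fit$loglik, count_parameters(ip_fit$structure))
  idx <- grep("^rGE_", names(ip_rge_fit$theta_natural))
  est <- ip_rge_fit$theta_natural[idx]
  se <- if (is.null(ip_rge_fit$se)) rep(NA_real_, length(idx)) else
    ip_rge_fit$se[idx]
  zq <- qnorm(1 - (1 - level) / 2)
  excl0 <- abs(est) - zq * se > 0
  rge_tab <- data.frame(parameter = names(est), estimate = unname(est),
                        se = unname(se), z = unname(est / se),
                        p_wald = 2 * pnorm(-abs(unname(est / se))),
                        ci_excludes_zero = unname(excl0),
                        stringsAsFactors = FALSE)
  supported <- (aic_improves || tst$p < 0.05) &&
    length(excl0) > 0 && all(excl0, na.rm = FALSE) && !anyNA(excl0)
  list(supported = isTRUE(supported), aic_improves = aic_improves,
       lrt = tst, rge = rge_tab)
}
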