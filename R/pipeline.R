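# Data-driven model building -------------------------------------------------

#' Predict the number of latent factors from a correlation matrix
#'
#' Kaiser's criterion (eigenvalues > 1) and an automated Cattell scree test
#' (elbow at the maximum acceleration, i.e. largest second difference, of
#' the descending eigenvalue sequence; factors retained = elbow index - 1).
#' The Kaiser count is primary; when the two heuristics disagree both
#' candidate counts are returned so downstream model fits can be compared
#' by AIC.
#'
#' @param corr_matrix correlation matrix (symmetric; eigenvalues below
#'   -1e-6 are an error).
#' @return List with `n_kaiser`, `n_cattell`, `chosen` (= `n_kaiser`; 0 is
#'   flagged degenerate), `candidates` (unique counts >= 1), `eigenvalues`,
#'   `agree`, `degenerate`.
#' @export
predict_n_factors <- function(corr_matrix) {
  R <- as.matrix(corr_matrix)
  if (max(abs(R - t(R))) > 1e-8) stop("correlation matrix not symmetric")
  ev <- eigen(0.5 * (R + t(R)), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-6)
    stop("matrix not positive semi-definite (min eigenvalue ",
         format(min(ev)), ")")
  n_kaiser <- sum(ev > 1)
  k <- length(ev)
  if (k >= 3) {
    acc <- ev[3:k] - 2 * ev[2:(k - 1)] + ev[1:(k - 2)]  # at positions 2..k-1
    elbow <- which.max(acc) + 1L
    n_cattell <- elbow - 1L
  } else n_cattell <- n_kaiser
  degenerate <- n_kaiser == 0
  list(n_kaiser = n_kaiser, n_cattell = n_cattell, chosen = n_kaiser,
       candidates = sort(unique(pmax(c(n_kaiser, n_cattell), 1L))),
       eigenvalues = ev, agree = n_kaiser == n_cattell,
       degenerate = degenerate)
}

#' Exploratory factor-analysis loading pattern
#'
#' ML exploratory factor analysis (oblique promax rotation for two or more
#' factors) of a correlation/covariance matrix; the returned mask frees the
#' loading of trait j on factor f where the absolute rotated loading is at
#' least `loading_threshold` (0.3, the conventional salience cut-off in
#' this literature). Traits with no freed common loading keep their
#' specific factor. On a Heywood case or non-convergence the factor count
#' is reduced by one and the retry is logged.
#'
#' @param mat correlation or covariance matrix.
#' @param n_factors number of factors to extract.
#' @param loading_threshold salience threshold for freeing a loading.
#' @param n_obs observations behind `mat` (enables the ML machinery).
#' @return List with `pattern` (list of trait-index vectors per factor),
#'   `mask` (k x n logical), `loadings`, `n_factors` (possibly reduced),
#'   `notes`.
#' @export
efa_pattern <- function(mat, n_factors, loading_threshold = 0.3,
                        n_obs = 1000) {
  R <- cov2cor(as.matrix(mat))
  k <- nrow(R)
  tn <- colnames(R) %||% paste0("trait", seq_len(k))
  # guard against slightly non-PD inputs (e.g. Cholesky-derived rg matrices)
  ev <- eigen(R, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    R <- ev$vectors %*% (pmax(ev$values, 1e-6) * t(ev$vectors))
    R <- cov2cor(R)
  }
  notes <- character(0)
  nf <- max(1L, as.integer(n_factors))
  fa <- NULL
  while (nf >= 1) {
    fa <- tryCatch(
      factanal(covmat = R, factors = nf, n.obs = n_obs,
               rotation = if (nf > 1) "promax" else "none"),
      error = function(e) e)
    if (!inherits(fa, "error")) {
      heywood <- any(fa$uniquenesses < 1e-3)
      if (!heywood) break
      notes <- c(notes, sprintf("Heywood case at %d factors; retrying with %d",
                                nf, nf - 1L))
    } else {
      notes <- c(notes, sprintf("EFA failed at %d factors (%s); retrying with %d",
                                nf, conditionMessage(fa), nf - 1L))
    }
    nf <- nf - 1L
    if (nf == 0) stop("exploratory factor analysis failed for all factor counts")
  }
  L <- matrix(unclass(fa$loadings), k, nf)
  mask <- abs(L) >= loading_threshold
  if (all(!mask))
    notes <- c(notes,
               "no loading reached the threshold: all traits specific-only (unidentified)")
  pattern <- lapply(seq_len(nf), function(f) which(mask[, f]))
  names(pattern) <- paste0("F", seq_len(nf))
  dimnames(L) <- list(tn, names(pattern))
  list(pattern = pattern, mask = mask, loadings = L, n_factors = nf,
       notes = notes)
}

# reorder E-side factors so each matches the A-side factor with the largest
# trait-set overlap (for index-matched rGE pairs)
match_factor_order <- function(pattern_A, pattern_E) {
  nA <- length(pattern_A); nE <- length(pattern_E)
  if (nE < 2) return(pattern_E)
  ov <- outer(seq_len(nE), seq_len(nA), Vectorize(function(e, a)
    length(intersect(pattern_E[[e]], pattern_A[[a]]))))
  ord <- integer(0)
  left <- seq_len(nE)
  for (a in seq_len(min(nA, nE))) {
    best <- left[which.max(ov[left, a])]
    ord <- c(ord, best)
    left <- setdiff(left, best)
  }
  pattern_E[c(ord, left)]
}

log_step <- function(state, stage, ...) {
  rec <- c(list(stage = stage), list(...))
  state$log[[length(state$log) + 1L]] <- rec
  state
}

#' Run the data-driven GRM-SEM model-building pipeline
#'
#' The stepwise procedure: (1) fit the saturated Cholesky model; (2) predict
#' the latent genetic structure (PCA factor-count heuristics plus EFA of the
#' Cholesky-derived genetic correlation matrix) and fit the IPC model;
#' (3) predict the latent residual structure from the IPC-derived residual
#' correlation (PCA) and covariance (EFA) matrices and fit the IP model;
#' (4) compare all models against the Cholesky baseline (LRT/AIC/BIC/SRMR);
#' (5) fit bifactor variants to test factor independence; (6) extend the IP
#' model with rGE parameters between structurally matched A-E factor pairs,
#' starting from the IP estimates; (7) constrain small specific loadings
#' (|lambda| < `constrain_threshold`) and refit. The final model is the
#' best by AIC among admissible (SRMR <= `srmr_max`) candidates.
#'
#' @param Y n x k phenotype matrix (or [prepare_phenotypes()] table).
#' @param grm a [grm()] aligned to `Y`.
#' @param seed integer seed (restart perturbations).
#' @param n_restarts restarts per fit.
#' @param loading_threshold EFA salience cut-off.
#' @param constrain_threshold specific-loading constraint threshold.
#' @param srmr_max admissibility bound on SRMR.
#' @param rge logical: attempt the rGE extension.
#' @param bifactor logical: run the bifactor independence checks.
#' @return Object of class `"grmsem_pipeline"`: fitted models (`fits`),
#'   the comparison table (`comparison`), chosen factor counts, the final
#'   model name (`final`), and a replayable decision log (`log`).
#' @export
run_grmsem_pipeline <- function(Y, grm, seed = 1, n_restarts = 2,
                                loading_threshold = 0.3,
                                constrain_threshold = 0.05,
                                srmr_max = 0.08, rge = TRUE,
                                bifactor = TRUE) {
  if (inherits(Y, "phenotype_table")) Y <- Y$values
  Y <- as.matrix(Y)
  k <- ncol(Y)
  tn <- colnames(Y) %||% paste0("trait", seq_len(k))
  colnames(Y) <- tn
  state <- list(log = list(), fits = list(), k = k, trait_names = tn)

  fit1 <- function(st, start = NULL)
    grmsem_fit(Y, grm, st, start = start, n_restarts = n_restarts,
               seed = seed)
  # halt on optimiser failure; a near-singular information matrix (e.g. a
  # specific loading estimated at zero) is tolerated here because the
  # constraint step later fixes such loadings to zero
  require_converged <- function(fit, stage) {
    if (!fit$optim_ok)
      stop("pipeline halted: non-converged fit at stage '", stage, "' (",
           paste(fit$diagnostic, collapse = "; "), ")")
    fit
  }

  # (1) saturated Cholesky baseline
  st_chol <- make_structure("cholesky", k, trait_names = tn)
  state$fits$cholesky <- require_converged(fit1(st_chol), "cholesky")
  state <- log_step(state, "cholesky", n_params = count_parameters(st_chol),
                    loglik = state$fits$cholesky$loglik)

  # (2) genetic structure from the Cholesky-derived rg matrix -> IPC
  kerC <- sigma_kernels(st_chol, state$fits$cholesky$theta_raw)
  rg_mat <- cov2cor(kerC$CG + diag(1e-8, k))
  dimnames(rg_mat) <- list(tn, tn)
  pcaA <- predict_n_factors(rg_mat)
  nA_cands <- pcaA$candidates
  ipc_cand <- list()
  for (nA in nA_cands) {
    efaA <- efa_pattern(rg_mat, nA, loading_threshold,
                        n_obs = nrow(Y))
    patA <- lapply(efaA$pattern, function(ix) tn[ix])
    if (all(lengths(patA) == 0)) next
    patA <- patA[lengths(patA) > 0]
    st_ipc <- make_structure("ipc", k, nA = length(patA), pattern_A = patA,
                             trait_names = tn)
    ipc_cand[[paste0("ipc_nA", length(patA))]] <-
      list(fit = fit1(st_ipc), pattern_A = patA, efa = efaA)
  }
  if (!length(ipc_cand)) stop("pipeline halted: no identifiable genetic pattern")
  aics <- vapply(ipc_cand, function(x)
    aic_from_ll(x$fit$loglik, count_parameters(x$fit$structure)), 0)
  ipc_best <- ipc_cand[[which.min(aics)]]
  require_converged(ipc_best$fit, "ipc")
  pattern_A <- ipc_best$pattern_A
  nA <- length(pattern_A)
  state$fits$ipc <- ipc_best$fit
  state <- log_step(state, "genetic_structure", n_kaiser = pcaA$n_kaiser,
                    n_cattell = pcaA$n_cattell, candidates = nA_cands,
                    chosen_nA = nA, pattern_A = pattern_A,
                    efa_notes = ipc_best$efa$notes)

  # (3) residual structure from IPC residual matrices -> IP
  kerI <- sigma_kernels(state$fits$ipc$structure, state$fits$ipc$theta_raw)
  re_cov <- kerI$CI + diag(1e-8, k)
  dimnames(re_cov) <- list(tn, tn)
  re_cor <- cov2cor(re_cov)
  pcaE <- predict_n_factors(re_cor)
  ip_cand <- list()
  for (nE in pcaE$candidates) {
    efaE <- efa_pattern(re_cov, nE, loading_threshold, n_obs = nrow(Y))
    patE <- lapply(efaE$pattern, function(ix) tn[ix])
    patE <- patE[lengths(patE) > 0]
    if (!length(patE)) next
    patE <- match_factor_order(pattern_A, patE)
    names(patE) <- paste0("F", seq_along(patE))
    st_ip <- make_structure("ip", k, nA = nA, nE = length(patE),
                            pattern_A = pattern_A, pattern_E = patE,
                            trait_names = tn)
    ip_cand[[paste0("ip_nE", length(patE))]] <-
      list(fit = fit1(st_ip), pattern_E = patE, efa = efaE)
  }
  if (!length(ip_cand)) stop("pipeline halted: no identifiable residual pattern")
  aics <- vapply(ip_cand, function(x)
    aic_from_ll(x$fit$loglik, count_parameters(x$fit$structure)), 0)
  ip_best <- ip_cand[[which.min(aics)]]
  require_converged(ip_best$fit, "ip")
  pattern_E <- ip_best$pattern_E
  nE <- length(pattern_E)
  state$fits$ip <- ip_best$fit
  state <- log_step(state, "residual_structure", n_kaiser = pcaE$n_kaiser,
                    n_cattell = pcaE$n_cattell, candidates = pcaE$candidates,
                    chosen_nE = nE, pattern_E = pattern_E,
                    efa_notes = ip_best$efa$notes)

  # (5) bifactor independence checks
  if (bifactor) {
    st_bfA <- tryCatch(
      make_structure("bifactor_A", k, nA = nA, nE = nE,
                     pattern_A = pattern_A, pattern_E = pattern_E,
                     trait_names = tn), error = function(e) NULL)
    if (!is.null(st_bfA))
      state$fits$bifactor_A <- fit1(st_bfA)
    st_bfE <- tryCatch(
      make_structure("bifactor_E", k, nA = nA, nE = nE,
                     pattern_A = pattern_A, pattern_E = pattern_E,
                     trait_names = tn), error = function(e) NULL)
    if (!is.null(st_bfE))
      state$fits$bifactor_E <- fit1(st_bfE)
    state <- log_step(state, "bifactor_checks",
                      aic_ip = aic_from_ll(state$fits$ip$loglik,
                                           count_parameters(state$fits$ip$structure)),
                      aic_bifactor_A = if (is.null(state$fits$bifactor_A))
                        NA_real_ else
                          aic_from_ll(state$fits$bifactor_A$loglik,
                                      count_parameters(state$fits$bifactor_A$structure)),
                      aic_bifactor_E = if (is.null(state$fits$bifactor_E))
                        NA_real_ else
                          aic_from_ll(state$fits$bifactor_E$loglik,
                                      count_parameters(state$fits$bifactor_E$structure)))
  }

  # (6) rGE extension of the IP model, started from the IP estimates
  if (rge) {
    st_rge <- make_structure("ip", k, nA = nA, nE = nE,
                             pattern_A = pattern_A, pattern_E = pattern_E,
                             trait_names = tn, rge = TRUE)
    start_rge <- c(state$fits$ip$theta_raw, rep(0, sum(st_rge$rge$free)))
    state$fits$ip_rge <- fit1(st_rge, start = start_rge)
    ev <- rge_evidence(state$fits$ip, state$fits$ip_rge)
    state <- log_step(state, "rge_extension", supported = ev$supported,
                      lrt_p = ev$lrt$p, aic_improves = ev$aic_improves,
                      estimates = ev$rge$estimate)

    # (7) constrain small specific loadings and refit
    st_con <- constrain_small_loadings(st_rge, state$fits$ip_rge,
                                       threshold = constrain_threshold)
    if (count_parameters(st_con) < count_parameters(st_rge)) {
      start_con <- project_theta(st_rge, st_con, state$fits$ip_rge$theta_raw)
      state$fits$ip_rge_con <- fit1(st_con, start = start_con)
      state <- log_step(state, "constrain_small_loadings",
                        dropped = count_parameters(st_rge) -
                          count_parameters(st_con))
    }
  }

  # (4/final) comparison against the Cholesky baseline, admissibility, AIC
  state$comparison <- fit_comparison(state$fits, baseline = "cholesky")
  # bifactor fits are independence checks, not candidate final models
  adm <- state$comparison$srmr <= srmr_max &
    !grepl("^bifactor", state$comparison$model)
  cand <- state$comparison[adm, , drop = FALSE]
  if (nrow(cand) == 0) cand <- state$comparison
  final <- cand$model[which.min(cand$aic)]
  state$final <- final
  state$final_fit <- state$fits[[final]]
  state$nA <- nA; state$nE <- nE
  state$pattern_A <- pattern_A; state$pattern_E <- pattern_E
  state <- log_step(state, "final_selection", final = final,
                    admissible = state$comparison$model[adm])
  class(state) <- "grmsem_pipeline"
  state
}

#' @export
print.grmsem_pipeline <- function(x, ...) {
  cat("grmsem_pipeline:", length(x$fits), "fitted models; final =", x$final,
      sprintf("(nA=%d, nE=%d)\n", x$nA, x$nE))
  print(transform(x$comparison,
                  loglik = round(loglik, 2), aic = round(aic, 2),
                  bic = round(bic, 2), srmr = round(srmr, 4),
                  lrt_chi2 = round(lrt_chi2, 2), lrt_p = round(lrt_p, 3)))
  invisible(x)
}

#' Split-half phenotypic factor analysis
#'
#' Deterministic seeded split of the sample into two halves balanced for
#' per-row missingness; exploratory factor analysis (with the PCA
#' factor-count heuristics) of the pairwise-complete Pearson covariance of
#' half 1; confirmatory factor analysis of the implied pattern on half 2,
#' in correlated- and uncorrelated-factor variants, reporting
#' CFI/TLI/RMSEA/SRMR/AIC/BIC for each.
#'
#' @param Y n x k phenotype matrix (n >= 200).
#' @param seed split seed.
#' @param loading_threshold EFA salience cut-off for the CFA pattern.
#' @return List with the factor-count prediction (`pca`), the EFA
#'   (`efa`), both CFA fits (`cfa_correlated`, `cfa_uncorrelated`), their
#'   fit indices, and the split assignment.
#' @export
split_half_phenotypic_sem <- function(Y, seed = 1, loading_threshold = 0.3) {
  if (inherits(Y, "phenotype_table")) Y <- Y$values
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (n < 200) stop("need n >= 200 for the split-half analysis")
  set.seed(as.integer(seed) %% .Machine$integer.max)
  miss <- rowSums(is.na(Y))
  half <- integer(n)
  for (m in sort(unique(miss))) {     # stratified by missingness count
    idx <- sample(which(miss == m))
    half[idx] <- rep(1:2, length.out = length(idx))
  }
  S1 <- cov(Y[half == 1, , drop = FALSE], use = "pairwise.complete.obs")
  if (anyNA(S1))
    stop("a split half has insufficient complete pairs for the covariance")
  pca <- predict_n_factors(cov2cor(S1))
  nf <- max(1L, pca$chosen)
  efa <- efa_pattern(S1, nf, loading_threshold, n_obs = sum(half == 1))
  pattern <- efa$pattern[lengths(efa$pattern) > 0]
  Y2 <- Y[half == 2, , drop = FALSE]
  S2 <- cov(Y2, use = "pairwise.complete.obs")
  if (anyNA(S2))
    stop("a split half has insufficient complete pairs for the covariance")
  n2 <- sum(stats::complete.cases(Y2))
  cfa_cor <- fit_cfa(S2, n2, pattern, correlated = TRUE)
  cfa_unc <- fit_cfa(S2, n2, pattern, correlated = FALSE)
  list(pca = pca, efa = efa, split = half,
       cfa_correlated = cfa_cor, cfa_uncorrelated = cfa_unc,
       indices_correlated = phenotypic_fit_indices(cfa_cor),
       indices_uncorrelated = phenotypic_fit_indices(cfa_unc),
       aic = c(correlated = aic_from_ll(cfa_cor$loglik, cfa_cor$n_params),
               uncorrelated = aic_from_ll(cfa_unc$loglik, cfa_unc$n_params)),
       bic = c(correlated = bic_from_ll(cfa_cor$loglik, cfa_cor$n_params, n2),
               uncorrelated = bic_from_ll(cfa_unc$loglik, cfa_unc$n_params,
                                          n2)))
}
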