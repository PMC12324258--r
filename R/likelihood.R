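# Likelihood machinery -------------------------------------------------------
#
# The phenotypic covariance implied by a model structure is
#   Sigma_V = C_G (x) G  +  C_X (x) G^{1/2}  +  C_I (x) I_n
# with trait-level kernel coefficients
#   C_G = Lambda_A Phi_A Lambda_A'          (genomic)
#   C_I = Lambda_E Phi_E Lambda_E'          (residual)
#   C_X = Lambda_A Phicov' Lambda_E' + Lambda_E Phicov Lambda_A'
#         (gene-environment cross term; zero without rGE)
# The cross term arises from a joint Gaussian model in which common genetic
# factor scores carry the kernel G (scores G^{1/2} u with u standard normal)
# and residual factor scores the identity kernel, correlated through rGE;
# its G^{1/2} kernel keeps Sigma_V symmetric and positive semi-definite for
# any admissible rGE. Because GRM diagonals are 1, each individual's k x k
# diagonal block is C_G + C_X + C_I, i.e. variance a + e + 2cov(A,E).

sigma_kernels <- function(structure, theta) {
  m <- assemble_matrices(structure, theta)
  CG <- m$LambdaA %*% m$PhiA %*% t(m$LambdaA)
  CI <- m$LambdaE %*% m$PhiE %*% t(m$LambdaE)
  half <- m$LambdaE %*% m$Phicov %*% t(m$LambdaA)  # Cov(E-part, A-part)
  CX <- half + t(half)
  list(CG = 0.5 * (CG + t(CG)), CI = 0.5 * (CI + t(CI)), CX = CX,
       cross_half = t(half))  # cross_half[j,j] = per-trait Cov(A,E)_jj
}

#' Model-implied phenotypic covariance
#'
#' Builds the full nk x nk covariance of `vec(Y)` (traits stacked
#' column-wise over individuals). Without rGE this is
#' \eqn{(\Lambda_A \Phi_A \Lambda_A') \otimes G + (\Lambda_E \Phi_E
#' \Lambda_E') \otimes I}. With rGE the default `cross_kernel = "sqrtG"`
#' adds the symmetric cross term \eqn{C_X \otimes G^{1/2}};
#' `cross_kernel = "literal"` instead places \eqn{\Lambda_E \Phi_{cov}
#' \Lambda_A'} under \eqn{\otimes G} and its transpose under
#' \eqn{\otimes I}, and raises an error if the resulting matrix is not
#' symmetric (which happens for any GRM with nonzero off-diagonals).
#'
#' @param structure a [make_structure()] object.
#' @param theta parameter vector (raw scale for correlation entries).
#' @param G n x n GRM matrix (or a [grm()]).
#' @param cross_kernel `"sqrtG"` (default) or `"literal"`.
#' @return nk x nk symmetric covariance matrix.
#' @export
implied_sigma <- function(structure, theta, G,
                          cross_kernel = c("sqrtG", "literal")) {
  cross_kernel <- match.arg(cross_kernel)
  if (inherits(G, "grm")) G <- G$values
  n <- nrow(G)
  ker <- sigma_kernels(structure, theta)
  if (cross_kernel == "literal") {
    CGlit <- ker$CG + t(ker$cross_half)           # + Lambda_E Phicov Lambda_A'
    CIlit <- ker$CI + ker$cross_half              # + Lambda_A Phicov' Lambda_E'
    S <- kronecker(CGlit, G) + kronecker(CIlit, diag(n))
    asym <- max(abs(S - t(S)))
    if (asym > 1e-10)
      stop("literal cross-kernel convention yields an asymmetric covariance ",
           "(max asymmetry ", format(asym), "); use cross_kernel = 'sqrtG'")
    return(0.5 * (S + t(S)))
  }
  S <- kronecker(ker$CG, G) + kronecker(ker$CI, diag(n))
  if (any(ker$CX != 0)) {
    ed <- eigen(G, symmetric = TRUE)
    Gh <- ed$vectors %*% (sqrt(pmax(ed$values, 0)) * t(ed$vectors))
    S <- S + kronecker(ker$CX, Gh)
  }
  0.5 * (S + t(S))
}

mvn_loglik_chol <- function(x, S) {
  R <- tryCatch(chol(S), error = function(e) NULL)
  if (is.null(R)) return(-Inf)
  z <- backsolve(R, x, transpose = TRUE)
  -0.5 * length(x) * log(2 * pi) - sum(log(diag(R))) - 0.5 * sum(z^2)
}

#' Direct (dense) log-likelihood with missing-data support
#'
#' Multivariate-normal log-likelihood of the observed (non-missing)
#' subvector of `vec(Y)`, mean zero, covariance the corresponding rows and
#' columns of [implied_sigma()] (full-information treatment of missingness
#' by subsetting). Dense cost is O((nk)^3); intended for moderate n.
#'
#' @param structure,theta,G as in [implied_sigma()].
#' @param Y n x k phenotype matrix (`NA` = missing), rows aligned to `G`.
#' @param cross_kernel passed to [implied_sigma()].
#' @return Log-likelihood (`-Inf` if the implied covariance is not
#'   positive definite at `theta`).
#' @export
loglik_direct <- function(structure, theta, Y, G,
                          cross_kernel = c("sqrtG", "literal")) {
  if (inherits(G, "grm")) G <- G$values
  Y <- as.matrix(Y)
  stopifnot(nrow(Y) == nrow(G), ncol(Y) == structure$k)
  v <- as.vector(Y)
  obs <- !is.na(v)
  S <- implied_sigma(structure, theta, G, cross_kernel = cross_kernel)
  mvn_loglik_chol(v[obs], S[obs, obs, drop = FALSE])
}

#' Rotated fast-path log-likelihood (complete data)
#'
#' Exploits the Kronecker structure: with `G = U diag(d) U'` and
#' `Ytil = U'Y`, rows of `Ytil` are independent with covariance
#' `C_G d_i + C_X sqrt(d_i) + C_I`, reducing the likelihood to n
#' k-dimensional Gaussian densities (O(n k^3) per evaluation). Refuses
#' missing data; use [loglik_direct()] for incomplete phenotypes.
#'
#' @param structure,theta as in [implied_sigma()].
#' @param Y complete n x k phenotype matrix.
#' @param grm a [grm()] (eigendecomposed on the fly if needed).
#' @return Log-likelihood; equals [loglik_direct()] to ~1e-8.
#' @export
loglik_rotated <- function(structure, theta, Y, grm) {
  Y <- as.matrix(Y)
  if (anyNA(Y))
    stop("missing data present: the rotated path needs complete data ",
         "(use loglik_direct)")
  if (!inherits(grm, "grm")) grm <- grm(as.matrix(grm))
  grm <- grm_eigen(grm)
  Ytil <- crossprod(grm$eigen$vectors, Y)
  ker <- sigma_kernels(structure, theta)
  ll_eigen_cpp(Ytil, grm$eigen$values, ker$CG, ker$CX, ker$CI)
}

central_gradient <- function(fn, x, h = 1e-4) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    g[i] <- (fn(xp) - fn(xm)) / (2 * hi)
  }
  g
}

numeric_hessian <- function(fn, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(0, p, p)
  hi <- h * pmax(1, abs(x))
  f0 <- fn(x)
  for (i in seq_len(p)) {
    xp <- x; xp[i] <- x[i] + hi[i]
    xm <- x; xm[i] <- x[i] - hi[i]
    H[i, i] <- (fn(xp) - 2 * f0 + fn(xm)) / hi[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      xpp <- x; xpp[c(i, j)] <- x[c(i, j)] + hi[c(i, j)]
      xpm <- x; xpm[i] <- x[i] + hi[i]; xpm[j] <- x[j] - hi[j]
      xmp <- x; xmp[i] <- x[i] - hi[i]; xmp[j] <- x[j] + hi[j]
      xmm <- x; xmm[c(i, j)] <- x[c(i, j)] - hi[c(i, j)]
      H[i, j] <- H[j, i] <-
        (fn(xpp) - fn(xpm) - fn(xmp) + fn(xmm)) / (4 * hi[i] * hi[j])
    }
  }
  H
}

# data-informed heuristic start: split the (regularised) sample covariance
# evenly between the A and E parts
heuristic_start <- function(structure, Y) {
  k <- structure$k
  S <- cov(Y, use = "pairwise.complete.obs")
  S[!is.finite(S)] <- 0
  ed <- eigen(0.5 * (S + t(S)), symmetric = TRUE)
  S <- ed$vectors %*% (pmax(ed$values, 0.05 * mean(abs(ed$values))) *
                         t(ed$vectors))
  half_chol <- t(chol(S / 2))
  start_side <- function(side) {
    th <- numeric(0)
    if (side$type == "chol") {
      for (f in seq_len(side$n_common))
        th <- c(th, half_chol[side$common_free[, f], f])
    } else {
      m_j <- rowSums(side$common_free)  # factors each trait loads on
      v_j <- diag(S) / 2
      for (f in seq_len(side$n_common)) {
        idx <- which(side$common_free[, f])
        th <- c(th, sqrt(v_j[idx] / (2 * pmax(m_j[idx], 1))))
      }
      idx <- which(side$specific_free)
      th <- c(th, sqrt(v_j[idx] / 2))
      th <- c(th, rep(0, sum(side$corr_free & upper.tri(side$corr_free))))
    }
    th
  }
  c(start_side(structure$A), start_side(structure$E),
    rep(0, sum(structure$rge$free)))
}

#' Fit a GRM-SEM model by maximum likelihood
#'
#' Maximises the Gaussian log-likelihood of the phenotypes under the
#' Kronecker-structured covariance implied by `structure`, by quasi-Newton
#' (BFGS) iterations with central-difference gradients and multi-start
#' restarts (multiplicative N(1, 0.1^2) perturbations of the start values).
#' Complete data use the rotated eigen fast path; any missing entry switches
#' to the dense full-information path (cost O((nk)^3), practical up to a few
#' thousand observed entries). Standard errors come from the inverse
#' observed information (numerical Hessian at the optimum); correlation-type
#' parameters (factor correlations, rGE) are optimised on an unconstrained
#' scale and reported back-transformed with delta-method standard errors.
#'
#' @param Y n x k phenotype matrix (or a [prepare_phenotypes()] table);
#'   traits are assumed covariate-residualised with mean zero.
#' @param grm a [grm()] (or plain relatedness matrix) aligned to the rows of
#'   `Y`.
#' @param structure a [make_structure()] object.
#' @param start optional start vector (natural scale); default is a
#'   data-informed heuristic.
#' @param n_restarts number of optimisation starts (first start
#'   unperturbed).
#' @param seed integer seed controlling restart perturbations.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param compute_se logical; skip the Hessian for speed in simulation
#'   loops.
#' @param path `"auto"`, `"rotated"` or `"direct"`.
#' @param optim_factr `factr` tolerance handed to the bounded quasi-Newton
#'   optimiser (smaller = tighter; 1e2 gives log-likelihoods resolved to
#'   ~1e-7 relative); simulation loops may loosen it for speed.
#' @return An object of class `"grmsem_fit"`; see [summary.grmsem_fit()],
#'   [standardize()], [coef.grmsem_fit()], [logLik.grmsem_fit()].
#' @export
grmsem_fit <- function(Y, grm, structure, start = NULL, n_restarts = 5,
                       seed = 1, tol = 1e-3, compute_se = TRUE,
                       path = c("auto", "rotated", "direct"),
                       optim_factr = 1e2) {
  path <- match.arg(path)
  if (inherits(Y, "phenotype_table")) Y <- Y$values
  Y <- as.matrix(Y)
  if (!inherits(grm, "grm")) grm <- grm(as.matrix(grm))
  if (nrow(Y) != nrow(grm$values)) stop("Y rows must align with the GRM")
  if (ncol(Y) != structure$k) stop("trait count mismatch with structure")
  has_na <- anyNA(Y)
  if (path == "auto") path <- if (has_na) "direct" else "rotated"
  if (path == "rotated" && has_na)
    stop("rotated path requires complete data")
  np <- count_parameters(structure)

  # inadmissible parameter points (implied covariance not PD) get a large
  # finite penalty: the bounded quasi-Newton optimiser cannot handle Inf
  PENALTY <- 1e10
  if (path == "rotated") {
    grm <- grm_eigen(grm)
    Ytil <- crossprod(grm$eigen$vectors, Y)
    # frequency-centred GRMs are rank-deficient by construction; clamp the
    # numerically-zero tail so admissibility is decided by the model part
    d <- pmax(grm$eigen$values, 0)
    negll <- function(th) {
      ker <- sigma_kernels(structure, th)
      v <- -ll_eigen_cpp(Ytil, d, ker$CG, ker$CX, ker$CI)
      if (is.finite(v)) v else PENALTY
    }
  } else {
    negll <- function(th) {
      v <- -loglik_direct(structure, th, Y, grm$values)
      if (is.finite(v)) v else PENALTY
    }
  }
  grad <- function(th) central_gradient(negll, th)

  if (is.null(start)) start <- heuristic_start(structure, Y)
  if (length(start) != np) stop("start has wrong length")

  set.seed(as.integer(seed) %% .Machine$integer.max)
  # box constraints: loadings generously bounded (traits are standardised),
  # raw correlation parameters capped at |tanh(4)| ~ 0.9993 to keep the
  # observed information usable near the +-1 boundary
  cmask <- corr_param_mask(structure)
  lower <- ifelse(cmask, -4, -25)
  upper <- ifelse(cmask, 4, 25)
  best <- NULL
  for (r in seq_len(max(1, n_restarts))) {
    st <- if (r == 1) start else start * rnorm(np, 1, 0.1)
    st <- pmin(pmax(st, lower), upper)
    res <- tryCatch(
      optim(st, negll, gr = grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 1000, factr = optim_factr, pgtol = 0)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimisation starts failed")
  # polish: restarting the bounded quasi-Newton from the optimum resets its
  # curvature memory and typically drops the residual gradient further
  for (polish in 1:2) {
    g0 <- central_gradient(negll, best$par)
    ok0 <- !((best$par <= lower + 1e-6 & g0 > 0) |
               (best$par >= upper - 1e-6 & g0 < 0))
    if (max(abs(g0[ok0]), 0) <= tol) break
    res <- tryCatch(
      optim(best$par, negll, gr = grad, method = "L-BFGS-B",
            lower = lower, upper = upper,
            control = list(maxit = 1000, factr = optim_factr, pgtol = 0)),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$value) && res$value <= best$value)
      best <- res else break
  }

  theta_raw <- canonicalize_theta(structure, best$par)
  g <- grad(theta_raw)
  # project out gradient components blocked by an active box bound
  at_lo <- theta_raw <= lower + 1e-6; at_hi <- theta_raw >= upper - 1e-6
  g_proj <- g
  g_proj[at_lo & g > 0] <- 0   # negll increases inward: bound is active
  g_proj[at_hi & g < 0] <- 0
  gnorm <- max(abs(g_proj))
  diagnostic <- character(0)
  if (any(at_lo | at_hi))
    diagnostic <- c(diagnostic, paste0(
      "boundary-adjacent parameter(s): ",
      paste(parameter_names(structure)[at_lo | at_hi], collapse = ", ")))

  theta_nat <- theta_raw
  theta_nat[cmask] <- tanh(theta_raw[cmask])
  se <- vcov_nat <- NULL
  hess_pd <- TRUE
  if (compute_se) {
    H <- numeric_hessian(negll, theta_raw)
    ch <- tryCatch(chol(H), error = function(e) NULL)
    rc <- tryCatch(1 / kappa(H, exact = FALSE), error = function(e) 0)
    if (is.null(ch) || !is.finite(rc) || rc < 1e-10) {
      hess_pd <- FALSE
      diagnostic <- c(diagnostic,
                      "observed information near-singular or not positive definite (flat likelihood direction: unidentified A vs E split, or a loading at zero)")
      # pseudo-inverse: flat directions get huge, not garbage, variances
      eh <- eigen(0.5 * (H + t(H)), symmetric = TRUE)
      inv_ev <- ifelse(eh$values > 1e-12 * max(abs(eh$values), 1),
                       1 / eh$values, 0)
      vcov_raw <- eh$vectors %*% (inv_ev * t(eh$vectors))
    } else {
      vcov_raw <- chol2inv(ch)
    }
    jac <- ifelse(cmask, 1 - theta_nat^2, 1)  # d tanh / d raw
    vcov_nat <- vcov_raw * tcrossprod(jac)
    se <- sqrt(pmax(diag(vcov_nat), 0))
    dimnames(vcov_nat) <- list(parameter_names(structure),
                               parameter_names(structure))
  } else vcov_raw <- NULL
  optim_ok <- (best$convergence == 0) && (gnorm < tol)
  converged <- optim_ok && hess_pd
  if (gnorm >= tol)
    diagnostic <- c(diagnostic, sprintf("gradient max-norm %.3g >= tol %.3g",
                                        gnorm, tol))
  fit <- structure(list(
    structure = structure,
    theta_natural = setNames(theta_nat, parameter_names(structure)),
    theta_raw = theta_raw,
    se = if (is.null(se)) NULL else setNames(se, parameter_names(structure)),
    vcov_theta = vcov_nat,
    vcov_raw = vcov_raw,
    loglik = -best$value,
    converged = converged,
    optim_ok = optim_ok,
    information_pd = hess_pd,
    diagnostic = diagnostic,
    gradient_norm = gnorm,
    n_restarts_used = max(1, n_restarts),
    n_individuals = nrow(Y),
    n_observations = sum(!is.na(Y)),
    path = path,
    Y = Y, grm_ids = grm$individual_ids),
    class = "grmsem_fit")
  fit
}

#' Univariate SNP heritability by maximum likelihood
#'
#' Single-trait variance-component fit (a k = 1 Cholesky: one genetic and
#' one residual loading), with a likelihood-ratio test against the
#' residual-only model using the 50:50 chi-square 0/1 boundary mixture.
#' Missing phenotype rows are dropped together with the matching GRM rows.
#'
#' @param y numeric trait vector.
#' @param grm a [grm()] aligned to `y`.
#' @param ... passed to [grmsem_fit()].
#' @return List with `h2`, `se`, `p_lrt`, `loglik`, `loglik_null` and the
#'   underlying `fit`.
#' @export
fit_univariate_h2 <- function(y, grm, ...) {
  if (!inherits(grm, "grm")) grm <- grm(as.matrix(grm))
  keep <- !is.na(y)
  if (sum(keep) < 2) stop("need at least 2 non-missing individuals")
  if (!all(keep)) {
    grm <- subset_grm(grm, grm$individual_ids[keep])
    y <- y[keep]
  }
  Y <- matrix(y, ncol = 1)
  st1 <- make_structure("cholesky", k = 1, trait_names = "trait")
  st0 <- st1
  st0$A$common_free[1, 1] <- FALSE  # residual-only null model
  f1 <- grmsem_fit(Y, grm, st1, ...)
  f0 <- grmsem_fit(Y, grm, st0, ...)
  a <- f1$theta_natural[1]; e <- f1$theta_natural[2]
  h2 <- a^2 / (a^2 + e^2)
  se <- NA_real_
  if (!is.null(f1$vcov_theta)) {
    # delta method on h2 = a^2/(a^2+e^2)
    den <- (a^2 + e^2)^2
    gvec <- c(2 * a * e^2 / den, -2 * e * a^2 / den)
    se <- sqrt(max(0, drop(t(gvec) %*% f1$vcov_theta %*% gvec)))
  }
  chi2 <- max(0, 2 * (f1$loglik - f0$loglik))
  p <- 0.5 * pchisq(chi2, df = 1, lower.tail = FALSE)
  if (chi2 == 0) p <- 1  # estimate on the boundary
  list(h2 = unname(h2), se = se, p_lrt = p,
       loglik = f1$loglik, loglik_null = f0$loglik, fit = f1)
}
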