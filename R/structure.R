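# Model structures ----------------------------------------------------------
#
# A model structure describes, for each of the genomic (A) and residual (E)
# parts, which factor-loading positions are free, and whether gene-
# environment correlations (rGE) link common A and E factors. Each part is
# one of:
#   chol - saturated lower-triangular k x k loading matrix, no specifics
#   ip   - n_common common factors (sparse pattern) + diagonal specifics
#   bif  - bifactor: one general factor on all traits + group factors
#          (a sparse pattern) + diagonal specifics
# Factor variances are fixed to one (unit diagonal of Phi); factor
# correlations among common factors may be freed. Correlation-type
# parameters (factor correlations, rGE) are stored on a raw scale and mapped
# through tanh onto (-1, 1) when matrices are assembled.

side_spec <- function(type, k, trait_names, pattern = NULL,
                      factor_names = NULL, corr_free = FALSE) {
  if (type == "chol") {
    return(list(type = "chol", n_common = k,
                factor_names = paste0("C", seq_len(k)),
                common_free = lower.tri(matrix(TRUE, k, k), diag = TRUE),
                specific_free = NULL,
                corr_free = matrix(FALSE, k, k)))
  }
  if (is.null(pattern)) stop("a loading pattern is required for type ", type)
  pattern <- lapply(pattern, function(idx) {
    if (is.character(idx)) idx <- match(idx, trait_names)
    if (anyNA(idx) || any(idx < 1 | idx > k)) stop("bad trait in pattern")
    sort(unique(as.integer(idx)))
  })
  nf <- length(pattern)
  fnames <- factor_names %||% names(pattern) %||% paste0("F", seq_len(nf))
  cm <- matrix(FALSE, k, nf, dimnames = list(trait_names, fnames))
  for (f in seq_len(nf)) cm[pattern[[f]], f] <- TRUE
  if (type == "bif") {
    cm <- cbind(gen = rep(TRUE, k), cm)
    fnames <- c("gen", fnames)
    nf <- nf + 1L
  }
  cf <- matrix(FALSE, nf, nf)
  if (isTRUE(corr_free)) {cf[] <- TRUE; diag(cf) <- FALSE}
  if (type == "bif") {cf[] <- FALSE}  # bifactor factors orthogonal
  list(type = type, n_common = nf, factor_names = fnames,
       common_free = cm, specific_free = rep(TRUE, k), corr_free = cf)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a GRM-SEM model structure
#'
#' Builds the free-parameter bookkeeping for one model family:
#' \describe{
#'   \item{cholesky}{saturated lower-triangular A and E parts (the baseline
#'     model); `nA = nE = k`, no specific factors.}
#'   \item{ip}{Independent Pathway: `nA` common genetic and `nE` common
#'     residual factors (sparse loading patterns) plus diagonal specific
#'     genetic (AS) and residual (ES) factors.}
#'   \item{ipc}{IP genetic part, Cholesky residual part.}
#'   \item{cip}{Cholesky genetic part, IP residual part.}
#'   \item{bifactor_A}{A part gets one general factor loading on all traits
#'     plus the group factors in `pattern_A`; E part as in `ip`. Used to
#'     test the independence of identified genetic factors.}
#'   \item{bifactor_E}{mirrored on the residual side.}
#' }
#' Factor variances are fixed to one. With `rge = TRUE`, gene-environment
#' correlations are freed between common A and E factors only (never between
#' specific factors): `rge_pairs = "matched"` frees one correlation per
#' index-matched factor pair, `"all"` frees the full nE x nA block.
#'
#' @param kind one of `"cholesky"`, `"ip"`, `"ipc"`, `"cip"`,
#'   `"bifactor_A"`, `"bifactor_E"`.
#' @param k number of traits.
#' @param nA,nE numbers of common genetic / residual factors (where the part
#'   is not a Cholesky).
#' @param pattern_A,pattern_E loading patterns: a list, one element per
#'   factor, of trait indices or names loading on it. Defaults to all traits
#'   on every factor.
#' @param trait_names optional trait labels.
#' @param rge logical: free gene-environment correlations.
#' @param rge_pairs `"matched"` or `"all"`.
#' @param corr_A,corr_E logical: free the factor correlations among common
#'   A (E) factors.
#' @return An object of class `"grmsem_structure"`.
#' @export
make_structure <- function(kind = c("cholesky", "ip", "ipc", "cip",
                                    "bifactor_A", "bifactor_E"),
                           k, nA = NULL, nE = NULL,
                           pattern_A = NULL, pattern_E = NULL,
                           trait_names = paste0("trait", seq_len(k)),
                           rge = FALSE, rge_pairs = c("matched", "all"),
                           corr_A = FALSE, corr_E = FALSE) {
  kind <- match.arg(kind)
  rge_pairs <- match.arg(rge_pairs)
  k <- as.integer(k)
  full <- function(nf) {
    if (is.null(nf)) stop("factor count missing for kind ", kind)
    setNames(rep(list(seq_len(k)), nf), paste0("F", seq_len(nf)))
  }
  A_type <- switch(kind, cholesky = "chol", ip = "ip", ipc = "ip",
                   cip = "chol", bifactor_A = "bif", bifactor_E = "ip")
  E_type <- switch(kind, cholesky = "chol", ip = "ip", ipc = "chol",
                   cip = "ip", bifactor_A = "ip", bifactor_E = "bif")
  A <- if (A_type == "chol") side_spec("chol", k, trait_names) else
    side_spec(A_type, k, trait_names, pattern_A %||% full(nA),
              corr_free = corr_A)
  E <- if (E_type == "chol") side_spec("chol", k, trait_names) else
    side_spec(E_type, k, trait_names, pattern_E %||% full(nE),
              corr_free = corr_E)
  rge_free <- matrix(FALSE, E$n_common, A$n_common)
  if (rge) {
    if (A$type == "chol" || E$type == "chol")
      stop("rGE requires common factors on both the A and the E side")
    if (rge_pairs == "matched") {
      for (i in seq_len(min(A$n_common, E$n_common))) rge_free[i, i] <- TRUE
    } else rge_free[] <- TRUE
  }
  st <- structure(list(kind = kind, k = k, trait_names = trait_names,
                       A = A, E = E,
                       rge = list(enabled = rge, free = rge_free)),
                  class = "grmsem_structure")
  # identification: every trait needs at least one free loading somewhere
  free_per_trait <- rowSums(st$A$common_free) + rowSums(st$E$common_free) +
    (st$A$specific_free %||% rep(FALSE, k)) +
    (st$E$specific_free %||% rep(FALSE, k))
  if (any(free_per_trait == 0))
    stop("unidentified trait(s) with no free loading: ",
         paste(trait_names[free_per_trait == 0], collapse = ", "))
  st
}

n_cols_side <- function(side, k) {
  side$n_common + if (is.null(side$specific_free)) 0L else k
}

side_param_names <- function(side, part, trait_names) {
  k <- length(trait_names)
  nm <- character(0)
  cm <- side$common_free
  for (f in seq_len(side$n_common))
    nm <- c(nm, sprintf("lambda%s_%s.%s", part, trait_names[cm[, f]],
                        side$factor_names[f]))
  if (!is.null(side$specific_free))
    nm <- c(nm, sprintf("lambda%sS_%s", part,
                        trait_names[side$specific_free]))
  if (any(side$corr_free)) {
    ut <- which(upper.tri(side$corr_free) & side$corr_free, arr.ind = TRUE)
    nm <- c(nm, sprintf("r%s_%s.%s", tolower(part),
                        side$factor_names[ut[, 1]],
                        side$factor_names[ut[, 2]]))
  }
  nm
}

#' Count free parameters of a model structure
#'
#' Free loading positions (common and specific), free factor correlations,
#' and rGE parameters. For a Cholesky structure with k traits this is
#' k(k+1).
#'
#' @param structure a [make_structure()] object.
#' @return Integer parameter count.
#' @export
count_parameters <- function(structure) {
  stopifnot(inherits(structure, "grmsem_structure"))
  cnt_side <- function(s)
    sum(s$common_free) + sum(s$specific_free %||% 0) +
      sum(s$corr_free & upper.tri(s$corr_free))
  cnt_side(structure$A) + cnt_side(structure$E) + sum(structure$rge$free)
}

#' Parameter labels of a model structure
#'
#' One label per free parameter, in the canonical packing order: A common
#' loadings (by factor), A specifics, A factor correlations, then the E
#' side likewise, then rGE entries.
#'
#' @param structure a [make_structure()] object.
#' @return Character vector of length [count_parameters()].
#' @export
parameter_names <- function(structure) {
  nm <- c(side_param_names(structure$A, "A", structure$trait_names),
          side_param_names(structure$E, "E", structure$trait_names))
  if (any(structure$rge$free)) {
    ix <- which(structure$rge$free, arr.ind = TRUE)
    nm <- c(nm, sprintf("rGE_%s.%s",
                        structure$E$factor_names[ix[, 1]],
                        structure$A$factor_names[ix[, 2]]))
  }
  nm
}

# which theta entries are correlation-type (raw scale, tanh-mapped)
corr_param_mask <- function(structure) {
  msk_side <- function(s)
    c(rep(FALSE, sum(s$common_free) + sum(s$specific_free %||% 0)),
      rep(TRUE, sum(s$corr_free & upper.tri(s$corr_free))))
  c(msk_side(structure$A), msk_side(structure$E),
    rep(TRUE, sum(structure$rge$free)))
}

# natural-scale parameters -> raw optimiser scale (correlations via atanh)
nat_to_raw <- function(structure, theta) {
  cm <- corr_param_mask(structure)
  theta[cm] <- atanh(theta[cm])
  theta
}

# which theta entries are specific loadings (for the constraint step)
specific_param_mask <- function(structure, part = c("A", "E")) {
  part <- match.arg(part)
  msk_side <- function(s, on)
    c(rep(FALSE, sum(s$common_free)),
      rep(on, sum(s$specific_free %||% 0)),
      rep(FALSE, sum(s$corr_free & upper.tri(s$corr_free))))
  c(msk_side(structure$A, part == "A"), msk_side(structure$E, part == "E"),
    rep(FALSE, sum(structure$rge$free)))
}

assemble_side <- function(side, k, theta, pos) {
  nc <- n_cols_side(side, k)
  L <- matrix(0, k, nc)
  for (f in seq_len(side$n_common)) {
    idx <- which(side$common_free[, f])
    L[idx, f] <- theta[pos + seq_along(idx)]
    pos <- pos + length(idx)
  }
  if (!is.null(side$specific_free)) {
    idx <- which(side$specific_free)
    L[cbind(idx, side$n_common + idx)] <- theta[pos + seq_along(idx)]
    pos <- pos + length(idx)
  }
  Phi <- diag(nc)
  if (any(side$corr_free)) {
    ut <- which(upper.tri(side$corr_free) & side$corr_free, arr.ind = TRUE)
    for (r in seq_len(nrow(ut))) {
      v <- tanh(theta[pos + r])
      Phi[ut[r, 1], ut[r, 2]] <- Phi[ut[r, 2], ut[r, 1]] <- v
    }
    pos <- pos + nrow(ut)
  }
  list(Lambda = L, Phi = Phi, pos = pos)
}

#' Assemble model matrices from a parameter vector
#'
#' Realises the loading matrices \eqn{\Lambda_A} (k x (nA+k) for IP-type
#' parts, k x k for Cholesky parts) and \eqn{\Lambda_E}, the factor
#' covariance matrices \eqn{\Phi_A}, \eqn{\Phi_E} (unit diagonal; free
#' off-diagonals among common factors only) and the gene-environment block
#' \eqn{\Phi_{cov(A,E)}} (nonzero only in the common-factor block; zero
#' when rGE is disabled).
#'
#' @param structure a [make_structure()] object.
#' @param theta numeric vector of length [count_parameters()]
#'   (correlation-type entries on the raw scale; see [parameter_names()]).
#' @return List with elements `LambdaA`, `LambdaE`, `PhiA`, `PhiE`,
#'   `Phicov` (rows index E factors, columns A factors).
#' @export
assemble_matrices <- function(structure, theta) {
  stopifnot(inherits(structure, "grmsem_structure"))
  np <- count_parameters(structure)
  if (length(theta) != np)
    stop("theta has length ", length(theta), ", expected ", np)
  k <- structure$k
  a <- assemble_side(structure$A, k, theta, 0L)
  e <- assemble_side(structure$E, k, theta, a$pos)
  cA <- ncol(a$Lambda); cE <- ncol(e$Lambda)
  Phicov <- matrix(0, cE, cA)
  pos <- e$pos
  if (any(structure$rge$free)) {
    ix <- which(structure$rge$free, arr.ind = TRUE)
    for (r in seq_len(nrow(ix)))
      Phicov[ix[r, 1], ix[r, 2]] <- tanh(theta[pos + r])
    pos <- pos + nrow(ix)
  }
  rownames(a$Lambda) <- rownames(e$Lambda) <- structure$trait_names
  list(LambdaA = a$Lambda, LambdaE = e$Lambda,
       PhiA = a$Phi, PhiE = e$Phi, Phicov = Phicov)
}

# inverse of assemble_matrices over the free masks (correlations -> raw)
flatten_matrices <- function(structure, mats) {
  k <- structure$k
  take_side <- function(side, L, Phi) {
    th <- numeric(0)
    for (f in seq_len(side$n_common))
      th <- c(th, L[side$common_free[, f], f])
    if (!is.null(side$specific_free)) {
      idx <- which(side$specific_free)
      th <- c(th, L[cbind(idx, side$n_common + idx)])
    }
    if (any(side$corr_free)) {
      ut <- which(upper.tri(side$corr_free) & side$corr_free, arr.ind = TRUE)
      th <- c(th, atanh(Phi[ut]))
    }
    th
  }
  th <- c(take_side(structure$A, mats$LambdaA, mats$PhiA),
          take_side(structure$E, mats$LambdaE, mats$PhiE))
  if (any(structure$rge$free)) {
    ix <- which(structure$rge$free, arr.ind = TRUE)
    th <- c(th, atanh(mats$Phicov[ix]))
  }
  unname(th)
}

# Sign conventions making the ML representative unique: Cholesky diagonal
# and specific loadings non-negative; each common factor's largest-magnitude
# loading positive (flipping the matching rGE entries with it).
canonicalize_theta <- function(structure, theta) {
  mats <- assemble_matrices(structure, theta)
  fix_side <- function(side, L, other_rge = NULL, rge_margin = 1) {
    flips <- rep(1, side$n_common)
    if (side$type == "chol") {
      for (f in seq_len(side$n_common))
        if (L[f, f] < 0) {L[, f] <- -L[, f]; flips[f] <- -1}
    } else {
      for (f in seq_len(side$n_common)) {
        idx <- which(side$common_free[, f])
        if (length(idx) && L[idx[which.max(abs(L[idx, f]))], f] < 0) {
          L[, f] <- -L[, f]; flips[f] <- -1
        }
      }
      sp <- which(side$specific_free)
      neg <- sp[L[cbind(sp, side$n_common + sp)] < 0]
      L[cbind(neg, side$n_common + neg)] <-
        -L[cbind(neg, side$n_common + neg)]
    }
    list(L = L, flips = flips)
  }
  a <- fix_side(structure$A, mats$LambdaA)
  e <- fix_side(structure$E, mats$LambdaE)
  mats$LambdaA <- a$L; mats$LambdaE <- e$L
  # propagate factor sign flips into factor correlations and rGE
  flip_phi <- function(Phi, flips) {
    s <- c(flips, rep(1, nrow(Phi) - length(flips)))
    diag(s, nrow = length(s)) %*% Phi %*% diag(s, nrow = length(s))
  }
  mats$PhiA <- flip_phi(mats$PhiA, a$flips)
  mats$PhiE <- flip_phi(mats$PhiE, e$flips)
  sE <- c(e$flips, rep(1, nrow(mats$Phicov) - length(e$flips)))
  sA <- c(a$flips, rep(1, ncol(mats$Phicov) - length(a$flips)))
  mats$Phicov <- diag(sE, nrow(mats$Phicov)) %*% mats$Phicov %*%
    diag(sA, ncol(mats$Phicov))
  flatten_matrices(structure, mats)
}

#' Constrain small specific loadings to zero
#'
#' Moves every free specific loading (AS and ES) whose absolute estimate
#' falls below `threshold` (default 0.05, the convention for loadings
#' explaining little variance) out of the free-parameter set, fixed at
#' zero. The parameter count decreases accordingly.
#'
#' @param structure a [make_structure()] object.
#' @param fit a [grmsem_fit()] estimated under `structure` (or a numeric
#'   theta vector on the natural scale).
#' @param threshold absolute loading threshold.
#' @param parts which specific blocks to screen (`"A"`, `"E"` or both).
#' @return A new `grmsem_structure` with the small specifics fixed to 0.
#' @export
constrain_small_loadings <- function(structure, fit, threshold = 0.05,
                                     parts = c("A", "E")) {
  est <- if (is.numeric(fit)) fit else fit$theta_natural
  stopifnot(length(est) == count_parameters(structure))
  orig <- structure  # masks must index the original parameter vector
  for (part in parts) {
    msk <- specific_param_mask(orig, part)
    side <- orig[[part]]
    if (is.null(side$specific_free)) next
    small <- abs(est) < threshold & msk
    if (!any(small)) next
    # map theta positions back to trait indices of this side's specifics
    sp_traits <- which(side$specific_free)
    sp_pos <- which(msk)
    drop_traits <- sp_traits[match(which(small), sp_pos)]
    structure[[part]]$specific_free[drop_traits] <- FALSE
  }
  structure
}

# drop theta entries whose positions were fixed when moving from structure
# `from` to the nested structure `to` (same kinds, subset of free specifics)
project_theta <- function(from, to, theta) {
  keep <- rep(TRUE, count_parameters(from))
  for (part in c("A", "E")) {
    msk_from <- which(specific_param_mask(from, part))
    sf_from <- which(from[[part]]$specific_free %||% logical(0))
    sf_to <- to[[part]]$specific_free %||% logical(0)
    keep[msk_from[!sf_to[sf_from]]] <- FALSE
  }
  theta[keep]
}

#' @export
print.grmsem_structure <- function(x, ...) {
  cat(sprintf("grmsem_structure '%s': k=%d traits, %d free parameters\n",
              x$kind, x$k, count_parameters(x)))
  fmt_side <- function(s, lab) {
    if (s$type == "chol")
      cat(sprintf("  %s: Cholesky (saturated, %d loadings)\n", lab,
                  sum(s$common_free)))
    else
      cat(sprintf("  %s: %s, %d common factor(s) [%s], %d common + %d specific loadings\n",
                  lab, if (s$type == "bif") "bifactor" else "IP",
                  s$n_common, paste(s$factor_names, collapse = ", "),
                  sum(s$common_free), sum(s$specific_free)))
  }
  fmt_side(x$A, "A")
  fmt_side(x$E, "E")
  if (x$rge$enabled)
    cat("  rGE:", sum(x$rge$free), "free gene-environment correlation(s)\n")
  invisible(x)
}

#' Serialise / restore a model structure
#'
#' Plain-list (YAML/JSON-ready) representation so loading patterns can be
#' declared in configuration files.
#'
#' @param structure a [make_structure()] object.
#' @return `structure_to_list` returns a plain list;
#'   `structure_from_list` rebuilds the `grmsem_structure`.
#' @export
structure_to_list <- function(structure) {
  side_pat <- function(s) {
    if (s$type == "chol") return(NULL)
    cm <- s$common_free
    drop_gen <- if (s$type == "bif") -1L else TRUE
    cols <- if (s$type == "bif") seq_len(s$n_common)[-1] else
      seq_len(s$n_common)
    setNames(lapply(cols, function(f) structure$trait_names[cm[, f]]),
             s$factor_names[cols])
  }
  list(kind = structure$kind, k = structure$k,
       trait_names = structure$trait_names,
       nA = if (structure$A$type == "chol") NULL else
         length(side_pat(structure$A)),
       nE = if (structure$E$type == "chol") NULL else
         length(side_pat(structure$E)),
       pattern_A = side_pat(structure$A), pattern_E = side_pat(structure$E),
       rge = structure$rge$enabled,
       corr_A = any(structure$A$corr_free),
       corr_E = any(structure$E$corr_free),
       fixed_specifics = list(
         A = structure$trait_names[!(structure$A$specific_free %||%
                                       rep(TRUE, structure$k))],
         E = structure$trait_names[!(structure$E$specific_free %||%
                                       rep(TRUE, structure$k))]))
}

#' @rdname structure_to_list
#' @param x a plain list as produced by `structure_to_list` (e.g. read back
#'   from YAML).
#' @export
structure_from_list <- function(x) {
  st <- make_structure(kind = x$kind, k = x$k, nA = x$nA, nE = x$nE,
                       pattern_A = x$pattern_A, pattern_E = x$pattern_E,
                       trait_names = x$trait_names,
                       rge = isTRUE(x$rge),
                       corr_A = isTRUE(x$corr_A), corr_E = isTRUE(x$corr_E))
  for (part in c("A", "E")) {
    fx <- x$fixed_specifics[[part]]
    if (length(fx) && !is.null(st[[part]]$specific_free))
      st[[part]]$specific_free[match(fx, st$trait_names)] <- FALSE
  }
  free_per_trait <- rowSums(st$A$common_free) + rowSums(st$E$common_free) +
    (st$A$specific_free %||% rep(FALSE, st$k)) +
    (st$E$specific_free %||% rep(FALSE, st$k))
  if (any(free_per_trait == 0))
    stop("unidentified trait(s) with no free loading: ",
         paste(st$trait_names[free_per_trait == 0], collapse = ", "))
  st
}
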