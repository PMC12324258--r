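#' Construct a genetic relationship matrix object
#'
#' @param values n x n symmetric numeric matrix of genome-wide relatedness.
#' @param individual_ids character vector of unique labels.
#' @param n_markers_per_pair optional n x n matrix of per-pair marker counts.
#' @return An object of class `"grm"`, a list with elements `values`,
#'   `individual_ids`, `n_markers_per_pair` and `eigen` (`NULL` until
#'   [grm_eigen()] is called).
#' @export
grm <- function(values, individual_ids = rownames(values),
                n_markers_per_pair = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("GRM must be square")
  if (!all(is.finite(values))) stop("GRM contains non-finite entries")
  if (max(abs(values - t(values))) > 1e-12 * max(1, max(abs(values))))
    stop("GRM not symmetric")
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(individual_ids)) stop("duplicate individual IDs")
  dimnames(values) <- list(individual_ids, individual_ids)
  structure(list(values = values, individual_ids = individual_ids,
                 n_markers_per_pair = n_markers_per_pair, eigen = NULL),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$values)
  od <- x$values[upper.tri(x$values)]
  cat(sprintf("grm: %d individuals; diag mean %.3f; off-diag sd %.2g%s\n",
              n, mean(diag(x$values)),
              if (n > 1) sd(od) else NA_real_,
              if (!is.null(x$eigen)) "; eigendecomposed" else ""))
  invisible(x)
}

#' Compute a genetic relationship matrix from genotypes
#'
#' Entry (j,k) is the mean over markers i of
#' \eqn{(x_{ij} - 2p_i)(x_{ik} - 2p_i) / (2 p_i (1-p_i))}, averaging only
#' over markers non-missing for both individuals (pairwise-complete, as in
#' PLINK/GCTA). Allele frequencies are estimated in-sample from non-missing
#' dosages. Monomorphic markers are dropped.
#'
#' @param genotypes a [genotype_matrix()] with at least 2 individuals.
#' @param block_size markers per accumulation block (memory control only).
#' @return A [grm()] with `n_markers_per_pair` filled in.
#' @export
compute_grm <- function(genotypes, block_size = 10000L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  X <- genotypes$values
  n <- nrow(X)
  if (n < 2) stop("need at least 2 individuals")
  p <- genotypes$allele_freqs
  poly <- is.finite(p) & p > 0 & p < 1
  if (!any(poly)) stop("no usable markers: all markers are monomorphic")
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  m <- ncol(X)
  acc <- matrix(0, n, n)
  cnt <- matrix(0, n, n)
  for (s in seq(1L, m, by = block_size)) {
    e <- min(s + block_size - 1L, m)
    Z <- sweep(X[, s:e, drop = FALSE], 2L, 2 * p[s:e], "-")
    Z <- sweep(Z, 2L, sqrt(2 * p[s:e] * (1 - p[s:e])), "/")
    obs <- !is.na(Z)
    Z[!obs] <- 0
    acc <- acc + tcrossprod(Z)
    cnt <- cnt + tcrossprod(obs * 1)
  }
  if (any(cnt == 0)) {
    bad <- which(cnt == 0, arr.ind = TRUE)
    stop("pair(s) with zero shared non-missing markers, e.g. individuals ",
         bad[1, 1], " and ", bad[1, 2])
  }
  grm(acc / cnt, individual_ids = genotypes$individual_ids,
      n_markers_per_pair = cnt)
}

#' Greedy relatedness pruning
#'
#' Repeatedly drops the individual participating in the most above-cutoff
#' pairs (ties broken by input order) until no retained off-diagonal exceeds
#' the cutoff.
#'
#' @param grm a [grm()].
#' @param cutoff positive relatedness threshold (the study convention is
#'   0.05 for samples of unrelated individuals).
#' @return Character vector of retained individual IDs, in input order.
#' @export
prune_related <- function(grm, cutoff = 0.05) {
  stopifnot(inherits(grm, "grm"), cutoff > 0)
  A <- grm$values
  diag(A) <- 0
  over <- abs(A) > cutoff  # symmetric adjacency of above-cutoff pairs
  keep <- rep(TRUE, nrow(A))
  repeat {
    deg <- rowSums(over[, keep, drop = FALSE]) * keep
    if (max(deg) == 0) break
    drop_i <- which.max(deg)  # first index among ties
    keep[drop_i] <- FALSE
    over[drop_i, ] <- FALSE
    over[, drop_i] <- FALSE
  }
  ids <- grm$individual_ids[keep]
  if (length(ids) < 2)
    warning("fewer than 2 individuals remain after pruning at cutoff ",
            cutoff)
  ids
}

#' Subset a GRM to a set of individuals
#'
#' @param grm a [grm()].
#' @param ids individual IDs to retain (order preserved as given).
#' @return A [grm()] restricted to `ids`.
#' @export
subset_grm <- function(grm, ids) {
  idx <- match(ids, grm$individual_ids)
  if (anyNA(idx)) stop("unknown individual IDs: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  npp <- grm$n_markers_per_pair
  if (!is.null(npp)) npp <- npp[idx, idx, drop = FALSE]
  grm(grm$values[idx, idx, drop = FALSE], grm$individual_ids[idx], npp)
}

#' Read / write GCTA binary GRM files
#'
#' The GCTA dialect stores the lower triangle (including the diagonal)
#' row-wise as little-endian 4-byte floats in `<prefix>.grm.bin`, per-pair
#' marker counts likewise in `<prefix>.grm.N.bin`, and IDs as two
#' whitespace-separated columns (FID IID) in `<prefix>.grm.id`.
#'
#' @param prefix path prefix.
#' @return `read_grm_gcta` returns a [grm()]; `write_grm_gcta` returns
#'   `prefix` invisibly.
#' @export
read_grm_gcta <- function(prefix) {
  fbin <- paste0(prefix, ".grm.bin"); fid <- paste0(prefix, ".grm.id")
  fN <- paste0(prefix, ".grm.N.bin")
  for (f in c(fbin, fid)) if (!file.exists(f)) stop("missing file: ", f)
  ids <- read.table(fid, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(ids)
  nrec <- n * (n + 1) / 2
  sz <- file.size(fbin)
  if (sz != 4 * nrec)
    stop("corrupt .grm.bin: ", sz, " bytes for n=", n,
         " (expected ", 4 * nrec, ")")
  vals <- readBin(fbin, "numeric", n = nrec, size = 4, endian = "little")
  V <- matrix(0, n, n)
  V[upper.tri(V, diag = TRUE)] <- vals  # column-wise upper == row-wise lower
  V <- V + t(V) - diag(diag(V), nrow = n)
  npp <- NULL
  if (file.exists(fN)) {
    if (file.size(fN) != 4 * nrec) stop("corrupt .grm.N.bin: size mismatch")
    nv <- readBin(fN, "numeric", n = nrec, size = 4, endian = "little")
    npp <- matrix(0, n, n)
    npp[upper.tri(npp, diag = TRUE)] <- nv
    npp <- npp + t(npp) - diag(diag(npp), nrow = n)
  }
  grm(V, individual_ids = as.character(ids[[2]]), n_markers_per_pair = npp)
}

#' @rdname read_grm_gcta
#' @param grm a [grm()] to write.
#' @export
write_grm_gcta <- function(grm, prefix) {
  stopifnot(inherits(grm, "grm"))
  n <- nrow(grm$values)
  tri <- upper.tri(grm$values, diag = TRUE)
  con <- file(paste0(prefix, ".grm.bin"), "wb")
  writeBin(grm$values[tri], con, size = 4, endian = "little")
  close(con)
  npp <- grm$n_markers_per_pair
  if (is.null(npp)) npp <- matrix(1, n, n)
  con <- file(paste0(prefix, ".grm.N.bin"), "wb")
  writeBin(npp[tri] * 1.0, con, size = 4, endian = "little")
  close(con)
  write.table(data.frame(grm$individual_ids, grm$individual_ids),
              paste0(prefix, ".grm.id"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Eigendecompose a GRM
#'
#' Caches the eigendecomposition (eigenvalues descending, orthonormal
#' eigenvectors) on the object; this enables the fast rotated likelihood
#' path for complete-data fits. Warns when eigenvalues fall below -1e-8
#' (GRM not positive semi-definite).
#'
#' @param grm a [grm()].
#' @return The same [grm()] with `eigen` populated (`values` = eigenvalues,
#'   `vectors` = eigenvectors).
#' @export
grm_eigen <- function(grm) {
  stopifnot(inherits(grm, "grm"))
  if (!is.null(grm$eigen)) return(grm)
  if (!all(is.finite(grm$values))) stop("GRM contains non-finite entries")
  ed <- eigen(grm$values, symmetric = TRUE)
  if (min(ed$values) < -1e-8)
    warning("GRM is not positive semi-definite (min eigenvalue ",
            format(min(ed$values)), ")")
  grm$eigen <- list(values = ed$values, vectors = ed$vectors)
  grm
}
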