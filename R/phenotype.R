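#' Reverse-code a trait
#'
#' Scores are aligned so that higher values indicate more difficulties;
#' ability-type measures (e.g. IQ, comprehension, pragmatic composites) are
#' therefore reverse-coded before transformation. Implemented as negation:
#' the subsequent rank-based transform depends only on ranks, so this is
#' equivalent to any `max - x` scheme. Missing values are preserved.
#'
#' @param scores numeric vector.
#' @return The reverse-coded vector.
#' @export
reverse_code <- function(scores) -as.numeric(scores)

#' Rank-based inverse-normal transform
#'
#' Maps values to normal quantiles of `(rank - offset) / (n - 2*offset + 1)`
#' with the Blom offset 3/8 by default; ties receive average ranks; missing
#' values stay missing.
#'
#' @param x numeric vector.
#' @param offset rank offset (3/8 = Blom).
#' @return Transformed vector, same length and missingness as `x`.
#' @export
rank_inverse_normal <- function(x, offset = 3 / 8) {
  out <- rep(NA_real_, length(x))
  ok <- !is.na(x)
  n <- sum(ok)
  if (n == 0) return(out)
  r <- rank(x[ok], ties.method = "average")
  out[ok] <- qnorm((r - offset) / (n - 2 * offset + 1))
  out
}

ols_residuals <- function(y, X) {
  # residuals of y on [1, X]; X may have zero columns
  n <- length(y)
  D <- cbind(rep(1, n), X)
  qr_d <- qr(D)
  if (qr_d$rank < ncol(D)) {
    keep <- qr_d$pivot[seq_len(qr_d$rank)]
    bad <- setdiff(seq_len(ncol(D)), keep)
    warning("rank-deficient covariate design; dropping column(s) ",
            paste(bad - 1L, collapse = ", "))
    D <- D[, keep, drop = FALSE]
    qr_d <- qr(D)
  }
  qr.resid(qr_d, y)
}

#' Double residualisation with rank-based normalisation
#'
#' The transformation applied to every trait before model fitting:
#' (1) OLS residuals of the trait on an intercept plus covariates,
#' (2) rank-based inverse-normal transform of those residuals (Blom offset,
#' average ranks for ties), (3) OLS residuals of the transformed values on
#' the same covariates again, so that covariate effects re-introduced by the
#' rank transform are removed. Rows missing in the trait or any covariate
#' stay missing.
#'
#' @param y numeric trait vector (missing allowed).
#' @param X numeric covariate matrix (or `NULL` / zero columns for none);
#'   rows align with `y`.
#' @param offset rank offset for the inverse-normal step.
#' @return Transformed vector with the same length and missingness pattern
#'   (union of trait and covariate missingness).
#' @export
double_residual_rank_transform <- function(y, X = NULL, offset = 3 / 8) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(numeric(0), n, 0)
  X <- as.matrix(X)
  if (nrow(X) != n) stop("covariate rows do not align with the trait")
  cc <- !is.na(y) & !apply(X, 1L, anyNA)
  if (sum(cc) <= ncol(X) + 2)
    stop("too few complete cases (", sum(cc), ") for ", ncol(X),
         " covariates")
  out <- rep(NA_real_, n)
  r1 <- ols_residuals(y[cc], X[cc, , drop = FALSE])
  # a numerically perfect fit leaves only rounding noise: treat as ties so
  # the rank transform maps everything to the same (zero) normal score
  if (max(abs(r1)) < 1e-10 * max(sd(y[cc]), 1)) r1[] <- 0
  z <- rank_inverse_normal(r1, offset = offset)
  out[cc] <- ols_residuals(z, X[cc, , drop = FALSE])
  out
}

#' Prepare a phenotype table for model fitting
#'
#' Applies [reverse_code()] to the named traits, then
#' [double_residual_rank_transform()] to every trait against the shared
#' covariate design. Covariates are matched to phenotype rows by ID.
#'
#' @param pheno data frame with an ID column plus one column per trait.
#' @param covar optional data frame with the same ID column plus covariate
#'   columns (age, age squared, sex, interactions, ancestry PCs, batch, ...).
#' @param reverse character vector of trait names to reverse-code.
#' @param id_col name of the ID column in both tables.
#' @return A list of class `"phenotype_table"` with `values` (n x k numeric
#'   matrix, transformed), `trait_labels`, `individual_ids` and
#'   `transform_log` (ordered record of applied steps).
#' @export
prepare_phenotypes <- function(pheno, covar = NULL, reverse = character(),
                               id_col = names(pheno)[1]) {
  ids <- as.character(pheno[[id_col]])
  if (anyDuplicated(ids)) stop("duplicate individual IDs in phenotype table")
  traits <- setdiff(names(pheno), id_col)
  Y <- as.matrix(pheno[traits])
  storage.mode(Y) <- "double"
  X <- NULL
  if (!is.null(covar)) {
    midx <- match(ids, as.character(covar[[id_col]]))
    X <- as.matrix(covar[midx, setdiff(names(covar), id_col), drop = FALSE])
    storage.mode(X) <- "double"
    keep <- apply(X, 2L, function(v) sd(v, na.rm = TRUE) > 0)
    X <- X[, keep, drop = FALSE]
  }
  log <- list()
  bad <- setdiff(reverse, traits)
  if (length(bad)) stop("unknown trait(s) to reverse-code: ",
                        paste(bad, collapse = ", "))
  for (tr in reverse) {
    Y[, tr] <- reverse_code(Y[, tr])
    log[[length(log) + 1L]] <- paste("reverse_code", tr)
  }
  for (tr in traits) {
    Y[, tr] <- double_residual_rank_transform(Y[, tr], X)
    log[[length(log) + 1L]] <- paste("double_residual_rank_transform", tr)
  }
  structure(list(values = Y, trait_labels = traits, individual_ids = ids,
                 transform_log = unlist(log)),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d individuals x %d traits (%.1f%% missing)\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))))
  cat("traits:", paste(x$trait_labels, collapse = ", "), "\n")
  invisible(x)
}
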