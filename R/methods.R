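# S3 methods for fitted models -----------------------------------------------

#' @export
print.grmsem_fit <- function(x, ...) {
  cat(sprintf("grmsem_fit '%s': k=%d traits, n=%d individuals (%d observations)\n",
              x$structure$kind, x$structure$k, x$n_individuals,
              x$n_observations))
  cat(sprintf("  log-likelihood %.2f, %d parameters, %s (%s path)\n",
              x$loglik, count_parameters(x$structure),
              if (x$converged) "converged" else "NOT converged", x$path))
  if (length(x$diagnostic)) cat("  note:", x$diagnostic[1], "\n")
  invisible(x)
}

#' Summarise a fitted GRM-SEM model
#'
#' Parameter estimates with standard errors, plus the standardised
#' variance decomposition from [standardize()].
#'
#' @param object a [grmsem_fit()].
#' @param ... unused.
#' @export
summary.grmsem_fit <- function(object, ...) {
  est <- data.frame(parameter = names(object$theta_natural),
                    estimate = unname(object$theta_natural),
                    se = if (is.null(object$se)) NA_real_ else
                      unname(object$se),
                    stringsAsFactors = FALSE)
  est$z <- est$estimate / est$se
  est$p_wald <- 2 * pnorm(-abs(est$z))
  out <- list(fit = object, parameters = est,
              standardized = tryCatch(standardize(object),
                                      error = function(e) NULL),
              aic = aic_from_ll(object$loglik,
                                count_parameters(object$structure)),
              bic = bic_from_ll(object$loglik,
                                count_parameters(object$structure),
                                object$n_individuals))
  class(out) <- "summary.grmsem_fit"
  out
}

#' @export
print.summary.grmsem_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  AIC %.2f, BIC %.2f\n\n", x$aic, x$bic))
  pp <- x$parameters
  pp$estimate <- round(pp$estimate, 4)
  pp$se <- round(pp$se, 4)
  pp$z <- round(pp$z, 2)
  pp$p_wald <- signif(pp$p_wald, 3)
  print(pp, row.names = FALSE)
  if (!is.null(x$standardized)) {
    cat("\nstandardised variance decomposition (per trait):\n")
    tn <- x$fit$structure$trait_names
    h2 <- x$standardized[match(paste0("snp_h2_", tn),
                               x$standardized$quantity), ]
    e2 <- x$standardized[match(paste0("e2_", tn), x$standardized$quantity), ]
    print(data.frame(trait = tn, snp_h2 = round(h2$estimate, 3),
                     se = round(h2$se, 3), e2 = round(e2$estimate, 3),
                     row.names = NULL))
  }
  invisible(x)
}

#' @export
coef.grmsem_fit <- function(object, ...) object$theta_natural

#' @export
vcov.grmsem_fit <- function(object, ...) object$vcov_theta

#' @export
logLik.grmsem_fit <- function(object, ...) {
  ll <- object$loglik
  attr(ll, "df") <- count_parameters(object$structure)
  attr(ll, "nobs") <- object$n_individuals
  class(ll) <- "logLik"
  ll
}

#' @export
nobs.grmsem_fit <- function(object, ...) object$n_individuals

#' Simulate phenotypes from a fitted model
#'
#' Parametric-bootstrap draws from the fitted covariance structure, given a
#' GRM (by default the draw is complete; pass `missing_rate` to emulate the
#' fitted data's missingness).
#'
#' @param object a [grmsem_fit()].
#' @param nsim number of draws.
#' @param seed integer seed.
#' @param grm a [grm()] aligned to the fitted sample (required).
#' @param missing_rate per-trait MCAR rate.
#' @param ... unused.
#' @return A list of `nsim` phenotype matrices.
#' @export
simulate.grmsem_fit <- function(object, nsim = 1, seed = 1, grm,
                                missing_rate = 0, ...) {
  if (missing(grm)) stop("a grm is required to simulate from the fit")
  theta_nat <- object$theta_natural
  lapply(seq_len(nsim), function(i) {
    sc <- simulation_scenario(object$structure, unname(theta_nat),
                              n_individuals = object$n_individuals,
                              missing_rate = missing_rate,
                              seed = as.integer(seed) + i - 1L)
    simulate_phenotypes(sc, grm)$values
  })
}

#' Plot a fitted GRM-SEM model
#'
#' Barplots of standardised genetic and residual factor loadings per trait
#' (common factors stacked side by side), the conventional loading-table
#' view of an IP-family fit.
#'
#' @param x a [grmsem_fit()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot.grmsem_fit <- function(x, ...) {
  std <- standardize(x)
  tn <- x$structure$trait_names
  pick_side <- function(part, side) {
    fn <- side$factor_names[seq_len(side$n_common)]
    M <- matrix(0, length(fn), length(tn), dimnames = list(fn, tn))
    for (f in seq_along(fn)) {
      q <- sprintf("lambda%s_%s.%s", part, tn, fn[f])
      v <- std$estimate[match(q, std$quantity)]
      M[f, ] <- ifelse(is.na(v), 0, v)
    }
    M
  }
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(pick_side("A", x$structure$A), beside = TRUE,
                    main = "standardised genetic loadings",
                    ylab = "loading", las = 2, ...)
  graphics::barplot(pick_side("E", x$structure$E), beside = TRUE,
                    main = "standardised residual loadings",
                    ylab = "loading", las = 2, ...)
  invisible(x)
}

#' @export
print.grmsem_std <- function(x, ...) {
  y <- x
  y$estimate <- round(y$estimate, 4)
  y$se <- round(y$se, 4)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
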