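#' Fit per-gene linear models
#'
#' Ordinary least squares of each gene's normalized expression on an
#' intercept plus the supplied covariate columns (as produced by
#' \code{\link{encode_covariates}}). All genes share one design, so the fit
#' is a single QR decomposition applied across the expression matrix.
#'
#' @param norm genes x samples normalized expression matrix.
#' @param covariates data.frame of model columns, samples in rows.
#' @param terms which covariate columns to include (default all, in order).
#' @return object of class \code{nd_fits}: \code{coefficients} (genes x
#'   terms, log2 fold-change per unit), \code{stdev_unscaled} (per-term
#'   unscaled standard error), \code{sigma2} (per-gene residual variance),
#'   \code{df} (residual degrees of freedom), \code{t_ordinary},
#'   \code{design}.
#' @export
fit_models <- function(norm, covariates, terms = colnames(covariates)) {
  y <- unclass(norm)
  covariates <- as.data.frame(covariates)[, terms, drop = FALSE]
  if (nrow(covariates) != ncol(y))
    stop("covariate rows must align with expression columns")
  if ("interaction" %in% terms &&
      !all(c("disease_c", "neuronal_c") %in% terms))
    stop("interaction term requires both disease_c and neuronal_c")
  x <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    drop <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         paste(drop, collapse = ", "))
  }
  n <- nrow(x); p <- ncol(x)
  beta <- t(qr.coef(qx, t(y)))            # genes x p
  res <- t(y) - x %*% t(beta)             # n x genes
  df <- n - p
  sigma2 <- colSums(res^2) / df
  xtxi <- chol2inv(qr.R(qx))
  u <- sqrt(diag(xtxi))
  names(u) <- colnames(x)
  t_ord <- beta / (sqrt(sigma2) %o% u)
  structure(list(coefficients = beta, stdev_unscaled = u, sigma2 = sigma2,
                 df = df, t_ordinary = t_ord, design = x),
            class = "nd_fits")
}

#' @export
print.nd_fits <- function(x, ...) {
  cat("Per-gene linear fits (nd_fits):", nrow(x$coefficients), "genes,",
      ncol(x$coefficients), "coefficients, residual df", x$df, "\n")
  invisible(x)
}

# Internal: invert the trigamma function by Newton iteration
# (solves trigamma(y) = x for y > 0, vectorized).
trigamma_inverse <- function(x, tol = 1e-8, maxit = 50) {
  y <- 0.5 + 1 / x
  for (i in seq_len(maxit)) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < tol) break
  }
  y
}

# Internal: estimate the prior df d0 and prior variance s0^2 from the
# gene-wise residual variances by moment matching on log(s^2).
estimate_prior <- function(sigma2, df) {
  s2 <- pmax(sigma2, 1e-300)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  rhs <- var(e) - trigamma(df / 2)
  if (!is.finite(rhs) || rhs <= 0) {
    # variances exchangeable with no excess spread: pool completely
    list(d0 = Inf, s0_2 = mean(s2))
  } else {
    d0 <- 2 * trigamma_inverse(rhs)
    list(d0 = d0, s0_2 = exp(emean + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Empirical-Bayes moderation of per-gene statistics
#'
#' Shrinks each gene's residual variance toward a common prior estimated
#' from all genes by moment matching on log residual variances (trigamma
#' inversion by Newton iteration, tolerance 1e-8). The posterior variance is
#' the convex combination \code{(d0*s0^2 + df*s^2) / (d0 + df)}; the
#' moderated t divides each coefficient by its unscaled standard error times
#' the posterior standard deviation, with p-values on \code{d0 + df} degrees
#' of freedom. When the gene-wise variances are exchangeable with no excess
#' spread the fit returns \code{d0 = Inf} and every posterior variance
#' equals \code{s0^2}; forcing \code{d0 = 0} recovers the ordinary t. The B
#' statistic (log-odds of differential expression) uses a prior proportion
#' \code{prior_prop} of differentially expressed genes and a coefficient
#' prior variance estimated from the 10 percent largest absolute moderated
#' t.
#'
#' @param fits an \code{\link{fit_models}} object.
#' @param prior_prop prior proportion of differentially expressed genes.
#' @param d0,s0_2 optional forced prior df / prior variance (both or
#'   neither); \code{d0 = 0} gives no shrinkage, \code{d0 = Inf} full
#'   shrinkage.
#' @return object of class \code{nd_effects} with genes x coefficient
#'   matrices \code{coefficients} (log2FC), \code{t} (moderated), \code{p},
#'   \code{fdr} (BH within coefficient), \code{B}; vectors \code{s2_post},
#'   \code{sigma2}; scalars \code{d0}, \code{s0_2}, \code{df},
#'   \code{df_total}.
#' @export
moderate <- function(fits, prior_prop = 0.01, d0 = NULL, s0_2 = NULL) {
  stopifnot(inherits(fits, "nd_fits"))
  G <- nrow(fits$coefficients)
  if (is.null(d0) != is.null(s0_2))
    stop("force both d0 and s0_2, or neither")
  if (is.null(d0) && G < 10)
    stop("prior estimation needs at least 10 genes")
  if (is.null(d0)) {
    pr <- estimate_prior(fits$sigma2, fits$df)
    d0 <- pr$d0; s0_2 <- pr$s0_2
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, G)
             else (d0 * s0_2 + fits$df * fits$sigma2) / (d0 + fits$df)
  tmod <- fits$coefficients /
    (sqrt(s2_post) %o% fits$stdev_unscaled)
  # cap the total df at the summed residual df: with d0 = Inf the evidence
  # about the common variance is still finite
  df_total <- min(fits$df + d0, G * fits$df)
  p <- 2 * pt(-abs(tmod), df = df_total)
  fdr <- apply(p, 2, p.adjust, method = "BH")

  # B statistic: log-odds of differential expression per coefficient
  u2 <- fits$stdev_unscaled^2
  B <- matrix(NA_real_, G, ncol(tmod), dimnames = dimnames(tmod))
  for (j in seq_len(ncol(tmod))) {
    tj <- tmod[, j]
    top <- order(-abs(tj))[seq_len(max(1L, ceiling(0.1 * G)))]
    v0 <- max(mean(pmax(fits$coefficients[top, j]^2 / s2_post[top] - u2[j],
                        0)), 1e-8)
    r <- (v0 + u2[j]) / u2[j]
    t2 <- tj^2
    kernel <- if (is.infinite(df_total)) t2 * (1 - 1 / r) / 2
              else (1 + df_total) / 2 *
                   log((t2 + df_total) / (t2 / r + df_total))
    B[, j] <- log(prior_prop / (1 - prior_prop)) - log(r) / 2 + kernel
  }
  structure(list(coefficients = fits$coefficients, t = tmod, p = p,
                 fdr = fdr, B = B, s2_post = s2_post, sigma2 = fits$sigma2,
                 d0 = d0, s0_2 = s0_2, df = fits$df, df_total = df_total,
                 stdev_unscaled = fits$stdev_unscaled),
            class = "nd_effects")
}

#' @export
print.nd_effects <- function(x, ...) {
  cat("Moderated effects (nd_effects):", nrow(x$t), "genes,",
      ncol(x$t), "coefficients\n")
  cat(sprintf("  prior df d0 = %s, prior variance s0^2 = %.4g\n",
              format(x$d0, digits = 4), x$s0_2))
  invisible(x)
}

#' @export
summary.nd_effects <- function(object, fdr_cut = 0.05, ...) {
  cat("Significant genes per coefficient at FDR <", fdr_cut, "\n")
  print(colSums(object$fdr < fdr_cut))
  invisible(object)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH false discovery rates with monotonicity enforcement.
#'
#' @param p vector of p-values in [0, 1].
#' @return adjusted values.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call differentially expressed genes
#'
#' Per-coefficient gene lists at a strict FDR threshold (gene called only
#' when FDR is strictly below the cut), with direction from the sign of the
#' estimate. Use \code{fdr_cut = 0.11} for the small-cohort microarray
#' profile.
#'
#' @param effects an \code{\link{moderate}} result.
#' @param coefs coefficients to report (default all non-intercept).
#' @param fdr_cut FDR threshold (strict <).
#' @return named list per coefficient of data.frames (gene, estimate, t,
#'   fdr, direction).
#' @export
call_de <- function(effects, coefs = NULL, fdr_cut = 0.05) {
  stopifnot(inherits(effects, "nd_effects"))
  if (is.null(coefs))
    coefs <- setdiff(colnames(effects$t), "(Intercept)")
  out <- lapply(coefs, function(cf) {
    sel <- which(effects$fdr[, cf] < fdr_cut)
    d <- data.frame(gene = rownames(effects$t)[sel],
                    estimate = effects$coefficients[sel, cf],
                    t = effects$t[sel, cf],
                    fdr = effects$fdr[sel, cf],
                    direction = ifelse(effects$coefficients[sel, cf] > 0,
                                       "up", "down"),
                    stringsAsFactors = FALSE, row.names = NULL)
    d[order(d$fdr), , drop = FALSE]
  })
  names(out) <- coefs
  out
}
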