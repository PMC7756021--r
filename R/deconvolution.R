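#' Estimate cell-type composition of bulk samples
#'
#' For each bulk sample, regresses the expression vector (over genes shared
#' with the signature) on the signature columns and renormalizes the
#' coefficients to sum to 1. The default backend is non-negative least
#' squares; \code{method = "nusvr"} uses linear-kernel nu-support-vector
#' regression on gene-standardized data with nu selected from
#' \{0.25, 0.5, 0.75\} by fit correlation and negative coefficients clipped
#' to zero before renormalization. The resulting fractions are shares of
#' mRNA, not of cells: a cell type with twice the mRNA content contributes
#' twice the share per cell. Fractions are invariant to positive rescaling
#' of the input sample.
#'
#' @param bulk genes x samples expression matrix (counts, CPM or
#'   intensities), or an \code{nd_bulk}.
#' @param signature an \code{\link{build_signature}} matrix (genes x types).
#' @param method "nnls" or "nusvr".
#' @param n_perm if > 0, per-sample permutation significance is computed via
#'   \code{\link{composition_significance}} with this many permutations.
#' @param seed seed for the permutation null.
#' @return object of class \code{nd_composition}: \code{fractions} (samples
#'   x types), \code{fit_cor} (per-sample Pearson correlation between the
#'   observed mixture and its reconstruction), \code{p} (per-sample
#'   permutation p, NA when \code{n_perm = 0}), \code{method},
#'   \code{shared_genes}.
#' @export
estimate_composition <- function(bulk, signature, method = c("nnls", "nusvr"),
                                 n_perm = 0, seed = 1L) {
  method <- match.arg(method)
  mat <- if (inherits(bulk, "nd_bulk")) bulk$counts else as.matrix(bulk)
  sig <- unclass(signature)
  shared <- intersect(rownames(mat), rownames(sig))
  if (length(shared) < 50)
    stop("fewer than 50 genes shared between bulk and signature")
  y_all <- mat[shared, , drop = FALSE]
  s <- sig[shared, , drop = FALSE]
  if (any(colSums(y_all) == 0)) stop("all-zero bulk sample")

  n <- ncol(y_all)
  fr <- matrix(NA_real_, n, ncol(s),
               dimnames = list(colnames(y_all), colnames(s)))
  fc <- numeric(n)
  for (j in seq_len(n)) {
    d <- deconvolve_one(y_all[, j], s, method)
    fr[j, ] <- d$fractions; fc[j] <- d$fit_cor
  }
  p <- rep(NA_real_, n)
  if (n_perm > 0)
    p <- vapply(seq_len(n), function(j)
      composition_significance(y_all[, j], s, n_perm = n_perm,
                               method = method, seed = seed + j),
      numeric(1))
  structure(list(fractions = fr, fit_cor = fc, p = p, method = method,
                 shared_genes = shared),
            class = "nd_composition")
}

#' Non-negative least squares (Lawson-Hanson active set)
#'
#' Solves \code{min ||A x - b||^2} subject to \code{x >= 0}. Exposed because
#' it is the default deconvolution backend.
#'
#' @param A design matrix (rows = observations).
#' @param b response vector.
#' @param maxit iteration cap.
#' @return non-negative coefficient vector of length \code{ncol(A)}.
#' @export
nnls_fit <- function(A, b, maxit = 50 * ncol(A) + 50) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- logical(n)
  tol <- 1e-10 * max(1, max(abs(crossprod(A, b))))
  for (it in seq_len(maxit)) {
    w <- as.vector(crossprod(A, b - A %*% x))
    w[passive] <- -Inf
    if (all(w <= tol)) break
    passive[which.max(w)] <- TRUE
    repeat {
      z <- numeric(n)
      zp <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      zp[is.na(zp)] <- 0
      z[passive] <- zp
      neg <- passive & z <= 0
      if (!any(neg)) { x <- z; break }
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive <- passive & x > 1e-12
      x[!passive] <- 0
    }
  }
  pmax(x, 0)
}

# Internal single-sample deconvolution shared by estimation and the
# permutation null.
deconvolve_one <- function(y, s, method) {
  if (method == "nnls") {
    coef <- nnls_fit(s, as.vector(y))
    recon <- s %*% coef
  } else {
    ys <- as.vector(scale(y))
    ss <- scale(s)
    best <- NULL
    for (nu in c(0.25, 0.5, 0.75)) {
      fit <- e1071::svm(ss, ys, type = "nu-regression", kernel = "linear",
                        nu = nu, scale = FALSE)
      w <- as.vector(t(fit$coefs) %*% fit$SV)
      rc <- ss %*% w
      r <- suppressWarnings(cor(ys, rc))
      if (is.na(r)) r <- -Inf
      if (is.null(best) || r > best$r) best <- list(w = w, r = r, rc = rc)
    }
    coef <- pmax(best$w, 0)  # clip negatives before renormalizing
    recon <- best$rc
    y <- scale(y)
  }
  tot <- sum(coef)
  frac <- if (tot > 0) coef / tot else rep(1 / ncol(s), ncol(s))
  r <- suppressWarnings(cor(as.vector(y), as.vector(recon)))
  list(fractions = frac, fit_cor = if (is.na(r)) 0 else r)
}

#' Permutation significance of a deconvolution fit
#'
#' Builds a null by permuting the sample's gene values and re-deconvolving;
#' the p-value is \code{(1 + #\{null fit correlation >= observed\}) /
#' (1 + n_perm)}, so the minimum attainable p is \code{1/(n_perm + 1)}.
#'
#' @param y expression vector over the signature's genes.
#' @param signature genes x types signature matrix (rows matching \code{y}).
#' @param n_perm number of permutations (>= 1).
#' @param method deconvolution backend.
#' @param seed permutation seed.
#' @return scalar p-value.
#' @export
composition_significance <- function(y, signature, n_perm = 100,
                                     method = "nnls", seed = 1L) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  s <- unclass(signature)
  y <- as.vector(y)
  obs <- deconvolve_one(y, s, method)$fit_cor
  with_seed(seed, {
    null <- vapply(seq_len(n_perm), function(b)
      deconvolve_one(sample(y), s, method)$fit_cor, numeric(1))
    (1 + sum(null >= obs)) / (1 + n_perm)
  })
}

#' Flag and filter samples with low estimated neuronal proportion
#'
#' Samples whose neuronal fraction falls strictly below \code{threshold}
#' (default 0.40) are flagged. Under the default \code{policy = "remove"}
#' they are removed; \code{policy = "keep"} retains them (the small-cohort
#' exception), still logging the flag.
#'
#' @param est an \code{nd_composition} (or samples x types fraction matrix
#'   with a "neuron" column).
#' @param threshold neuronal-fraction cut (strict <).
#' @param policy "remove" or "keep".
#' @param neuron_col name of the neuronal column.
#' @return list with \code{kept} (sample names), \code{log} (data.frame:
#'   sample, neuron_fraction, flagged, removed).
#' @export
filter_low_neuron_samples <- function(est, threshold = 0.40,
                                      policy = c("remove", "keep"),
                                      neuron_col = "neuron") {
  policy <- match.arg(policy)
  fr <- if (inherits(est, "nd_composition")) est$fractions else as.matrix(est)
  if (!neuron_col %in% colnames(fr)) stop("no neuronal column present")
  nf <- fr[, neuron_col]
  flagged <- nf < threshold
  removed <- flagged & policy == "remove"
  list(kept = rownames(fr)[!removed],
       log = data.frame(sample = rownames(fr), neuron_fraction = nf,
                        flagged = flagged, removed = removed,
                        row.names = NULL, stringsAsFactors = FALSE))
}

#' Benchmark estimated against true fractions
#'
#' Per cell type: Pearson correlation (with p-value), root-mean-square error
#' and bias (mean estimated minus true); plus an overall summary across all
#' entries.
#'
#' @param true,estimated samples x types fraction matrices of equal shape.
#' @return object of class \code{nd_benchmark}: \code{per_type} data.frame
#'   and \code{overall} list.
#' @export
benchmark_mixtures <- function(true, estimated) {
  true <- as.matrix(true); estimated <- as.matrix(estimated)
  if (!all(dim(true) == dim(estimated))) stop("shape mismatch")
  if (!is.null(colnames(true)) && !is.null(colnames(estimated)))
    estimated <- estimated[, colnames(true), drop = FALSE]
  per_type <- do.call(rbind, lapply(colnames(true), function(t) {
    ct <- suppressWarnings(cor.test(true[, t], estimated[, t]))
    data.frame(type = t,
               r = unname(ct$estimate), p = ct$p.value,
               rmse = sqrt(mean((estimated[, t] - true[, t])^2)),
               bias = mean(estimated[, t] - true[, t]),
               stringsAsFactors = FALSE)
  }))
  overall <- list(r = cor(as.vector(true), as.vector(estimated)),
                  rmse = sqrt(mean((estimated - true)^2)))
  structure(list(per_type = per_type, overall = overall),
            class = "nd_benchmark")
}

#' @export
print.nd_benchmark <- function(x, ...) {
  cat("Deconvolution benchmark (nd_benchmark)\n")
  print(x$per_type, row.names = FALSE)
  cat(sprintf("overall r = %.3f, RMSE = %.4f\n",
              x$overall$r, x$overall$rmse))
  invisible(x)
}

#' @export
print.nd_composition <- function(x, ...) {
  cat("Composition estimate (nd_composition,", x$method, "backend):",
      nrow(x$fractions), "samples x", ncol(x$fractions), "types over",
      length(x$shared_genes), "genes\n")
  print(utils::head(round(x$fractions, 3), 4))
  invisible(x)
}
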