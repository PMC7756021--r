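#' Per-cell quality-control metrics
#'
#' Computes, for every cell, the library size (total counts), the number of
#' expressed genes, and the fraction of counts from mitochondrial genes,
#' together with robust z-scores: deviation from the cross-cell median in
#' MAD units, with the MAD scaled by 1.4826 for consistency with a normal
#' standard deviation. Library size and gene counts are assessed on the log2
#' scale; the mitochondrial fraction on its natural scale. When a metric's
#' MAD is zero the robust z is 0 for cells at the median and +/-Inf
#' otherwise, and the metric is flagged.
#'
#' @param sc an \code{nd_reference} or a genes x cells count matrix.
#' @param mito_flag logical per gene; taken from \code{sc} when it is an
#'   \code{nd_reference}.
#' @return data.frame of class \code{nd_cellqc} with columns
#'   \code{lib_size}, \code{n_genes}, \code{mito_fraction},
#'   \code{z_lib}, \code{z_genes}, \code{z_mito}; attribute
#'   \code{zero_mad} names any degenerate metric.
#' @export
compute_cell_qc <- function(sc, mito_flag = NULL) {
  counts <- if (inherits(sc, "nd_reference")) sc$counts else as.matrix(sc)
  if (length(counts) == 0 || ncol(counts) == 0) stop("empty count matrix")
  if (is.null(mito_flag) && inherits(sc, "nd_reference"))
    mito_flag <- sc$mito_flag
  if (is.null(mito_flag)) mito_flag <- rep(FALSE, nrow(counts))

  lib <- colSums(counts)
  ngene <- colSums(counts > 0)
  mito <- if (any(mito_flag))
    colSums(counts[mito_flag, , drop = FALSE]) / pmax(lib, 1)
  else rep(0, ncol(counts))

  robust_z <- function(x) {
    med <- median(x); m <- mad(x, constant = 1.4826)
    if (m == 0) ifelse(x == med, 0, sign(x - med) * Inf) else (x - med) / m
  }
  l2l <- log2(lib + 1); l2g <- log2(ngene + 1)
  out <- data.frame(cell = colnames(counts), lib_size = lib, n_genes = ngene,
                    mito_fraction = mito, z_lib = robust_z(l2l),
                    z_genes = robust_z(l2g), z_mito = robust_z(mito),
                    row.names = colnames(counts), stringsAsFactors = FALSE)
  zero <- c(lib = mad(l2l) == 0, genes = mad(l2g) == 0, mito = mad(mito) == 0)
  attr(out, "zero_mad") <- names(zero)[zero]
  class(out) <- c("nd_cellqc", "data.frame")
  out
}

#' Filter low-quality cells
#'
#' Removes cells with robust z < -3 for library size, robust z < -3 for the
#' number of expressed genes, or robust z > 3 for the mitochondrial read
#' fraction. Metrics are those of \code{\link{compute_cell_qc}}; re-running
#' the filter after recomputing metrics on the kept cells can remove further
#' cells (the medians move), which is expected behaviour.
#'
#' @param metrics an \code{nd_cellqc}.
#' @param lib_cut,gene_cut lower robust-z cuts (default -3).
#' @param mito_cut upper robust-z cut for mitochondrial fraction (default 3).
#' @return list with \code{kept} (integer indices), \code{removed}
#'   (data.frame of removed cells with reasons).
#' @export
filter_cells <- function(metrics, lib_cut = -3, gene_cut = -3, mito_cut = 3) {
  stopifnot(inherits(metrics, "nd_cellqc"))
  bad_lib <- metrics$z_lib < lib_cut
  bad_gene <- metrics$z_genes < gene_cut
  bad_mito <- metrics$z_mito > mito_cut
  bad <- bad_lib | bad_gene | bad_mito
  reason <- vapply(seq_len(nrow(metrics)), function(i) {
    paste(c("low_library", "few_genes", "high_mito")[
      c(bad_lib[i], bad_gene[i], bad_mito[i])], collapse = ";")
  }, character(1))
  list(kept = which(!bad),
       removed = data.frame(cell = metrics$cell[bad],
                            reason = reason[bad], stringsAsFactors = FALSE))
}

#' Filter single-cell genes by mean CPM
#'
#' Keeps genes whose mean counts-per-million across cells strictly exceeds 1
#' (equivalently, log10 mean CPM > 0).
#'
#' @param sc an \code{nd_reference} or genes x cells count matrix.
#' @return integer indices of kept genes (named by gene).
#' @export
filter_genes_sc <- function(sc) {
  counts <- if (inherits(sc, "nd_reference")) sc$counts else as.matrix(sc)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("cells with zero library size; run cell QC first")
  cpm <- sweep(counts, 2, lib, "/") * 1e6
  keep <- which(rowMeans(cpm) > 1)
  keep
}

#' Decompose per-gene variance into technical and biological components
#'
#' On log2(CPM+1) expression, fits the mean-dependent trend of the variance
#' by local polynomial (loess) regression; the technical component of a gene
#' is the trend value at its mean, the biological component is the total
#' variance minus the technical component (exactly). A gene is retained when
#' its biological component is positive and a one-sided F-ratio of total to
#' technical variance (conservative df = cells - 1 on both sides) is
#' significant at BH FDR < \code{fdr}.
#'
#' @param sc an \code{nd_reference} or genes x cells count matrix.
#' @param genes optional gene subset (indices or names) to decompose.
#' @param fdr retention threshold on the BH-adjusted F-ratio p-value.
#' @param span loess span of the mean-variance trend.
#' @return data.frame of class \code{nd_vardecomp}: \code{mean},
#'   \code{total}, \code{technical}, \code{biological}, \code{p},
#'   \code{fdr}, \code{retain}.
#' @export
decompose_variance <- function(sc, genes = NULL, fdr = 0.05, span = 0.5) {
  counts <- if (inherits(sc, "nd_reference")) sc$counts else as.matrix(sc)
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (nrow(counts) < 20) stop("need at least 20 genes to fit the trend")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("cells with zero library size")
  le <- log2(sweep(counts, 2, lib, "/") * 1e6 + 1)
  mu <- rowMeans(le)
  v <- apply(le, 1, var)
  if (sd(mu) == 0 || all(v == 0)) stop("degenerate spread; cannot fit trend")
  fit <- tryCatch(
    loess(v ~ mu, span = span, degree = 1, family = "symmetric",
          control = loess.control(surface = "direct")),
    error = function(e) stop("mean-variance trend fit failed: ",
                             conditionMessage(e)))
  tech <- pmax(predict(fit, mu), 1e-8)
  bio <- v - tech
  df <- ncol(counts) - 1
  p <- pf(v / tech, df, df, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")
  out <- data.frame(mean = mu, total = v, technical = tech, biological = bio,
                    p = p, fdr = q, retain = bio > 0 & q < fdr,
                    row.names = rownames(counts))
  class(out) <- c("nd_vardecomp", "data.frame")
  out
}

#' Nearest shrunken centroid classification of cells
#'
#' Implements shrunken-centroid discrimination on log2(CPM+1) expression:
#' per-gene standardized class-centroid deviations are soft-thresholded by
#' \code{delta}, centroids reconstructed from the surviving deviations, and
#' each cell assigned the class with the smallest standardized squared
#' distance to a shrunken centroid. Class priors are uniform and ties are
#' broken by the fixed order of the training labels, so at full shrinkage
#' every cell is assigned the first class. Cells whose assignment disagrees
#' with their annotated label are reported as candidate misclassifications.
#'
#' @param train an \code{nd_reference} or genes x cells count matrix.
#' @param labels training labels (taken from \code{train$cell_type} for an
#'   \code{nd_reference}).
#' @param test genes x cells count matrix to classify; defaults to the
#'   training cells.
#' @param delta non-negative soft threshold.
#' @return list with \code{predicted} (label per test cell),
#'   \code{misclassified} (data.frame, only when test = train),
#'   \code{delta}, \code{n_nonzero_genes}.
#' @export
nsc_classify <- function(train, labels = NULL, test = NULL, delta = 0) {
  if (delta < 0) stop("delta must be non-negative")
  counts <- if (inherits(train, "nd_reference")) train$counts else as.matrix(train)
  if (is.null(labels) && inherits(train, "nd_reference"))
    labels <- train$cell_type
  types <- unique(labels)
  if (any(table(factor(labels, levels = types)) < 2))
    stop("every type needs at least 2 training cells")
  to_log <- function(m) log2(sweep(m, 2, pmax(colSums(m), 1), "/") * 1e6 + 1)
  x <- to_log(counts)
  self_test <- is.null(test)
  xt <- if (self_test) x else to_log(as.matrix(test))

  n <- ncol(x); K <- length(types)
  overall <- rowMeans(x)
  cent <- sapply(types, function(t) rowMeans(x[, labels == t, drop = FALSE]))
  nk <- as.vector(table(factor(labels, levels = types)))
  # pooled within-class standard deviation
  ss <- Reduce(`+`, lapply(seq_len(K), function(k) {
    xc <- x[, labels == types[k], drop = FALSE] - cent[, k]
    rowSums(xc^2)
  }))
  s <- sqrt(ss / (n - K))
  s0 <- median(s)
  mk <- sqrt(1 / nk - 1 / n)
  d <- sweep(cent - overall, 1, s + s0, "/")
  d <- sweep(d, 2, mk, "/")
  dshr <- sign(d) * pmax(abs(d) - delta, 0)
  cent_shr <- overall + sweep(sweep(dshr, 2, mk, "*"), 1, s + s0, "*")

  denom <- (s + s0)^2
  scores <- sapply(seq_len(K), function(k)
    colSums((xt - cent_shr[, k])^2 / denom))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  pred <- types[apply(scores, 1, which.min)]  # which.min: first = fixed order
  out <- list(predicted = pred, delta = delta,
              n_nonzero_genes = sum(rowSums(abs(dshr)) > 0))
  if (self_test) {
    dis <- which(pred != labels)
    cn <- colnames(x)
    if (is.null(cn)) cn <- sprintf("cell%04d", seq_len(ncol(x)))
    out$misclassified <- data.frame(cell = cn[dis],
                                    label = labels[dis],
                                    predicted = pred[dis],
                                    stringsAsFactors = FALSE)
  }
  out
}

#' Choose the NSC shrinkage threshold by cross-validation
#'
#' Evaluates a grid of \code{delta} values by k-fold cross-validation of
#' \code{\link{nsc_classify}} accuracy and returns the largest delta within
#' the best accuracy (preferring sparser classifiers on ties).
#'
#' @param train an \code{nd_reference} or count matrix.
#' @param labels training labels.
#' @param deltas candidate thresholds.
#' @param nfold folds.
#' @param seed fold-assignment seed.
#' @return list with \code{delta} (chosen), \code{accuracy} per candidate.
#' @export
nsc_cv_delta <- function(train, labels = NULL, deltas = seq(0, 4, by = 0.5),
                         nfold = 5, seed = 1) {
  counts <- if (inherits(train, "nd_reference")) train$counts else as.matrix(train)
  if (is.null(labels) && inherits(train, "nd_reference"))
    labels <- train$cell_type
  n <- ncol(counts)
  folds <- with_seed(seed, sample(rep_len(seq_len(nfold), n)))
  acc <- sapply(deltas, function(dl) {
    hits <- 0
    for (f in seq_len(nfold)) {
      tr <- folds != f
      if (min(table(labels[tr])) < 2) next
      pr <- nsc_classify(counts[, tr, drop = FALSE], labels[tr],
                         test = counts[, !tr, drop = FALSE], delta = dl)
      hits <- hits + sum(pr$predicted == labels[!tr])
    }
    hits / n
  })
  best <- max(acc)
  list(delta = max(deltas[acc == best]), accuracy = stats::setNames(acc, deltas))
}

#' Build a cell-type signature matrix
#'
#' Averages CPM expression per cell type over QC-passing cells, restricted to
#' retained genes that additionally pass a one-vs-rest specificity criterion:
#' a gene is kept when its top-type mean is at least \code{min_ratio} times
#' the second-highest type mean (CPM scale). All-zero rows are dropped. A
#' warning is emitted when two signature columns are (near-)identical, since
#' the specificity criterion then removes the genes that could distinguish
#' them.
#'
#' @param sc an \code{nd_reference} or genes x cells count matrix.
#' @param labels cell-type labels.
#' @param genes retained genes (indices or names), e.g. from
#'   \code{\link{decompose_variance}}.
#' @param min_ratio top-type to second-type mean ratio required (default 2).
#' @return genes x cell-types matrix of class \code{nd_signature}.
#' @export
build_signature <- function(sc, labels = NULL, genes = NULL, min_ratio = 2) {
  counts <- if (inherits(sc, "nd_reference")) sc$counts else as.matrix(sc)
  if (is.null(labels) && inherits(sc, "nd_reference"))
    labels <- sc$cell_type
  types <- unique(labels)
  if (any(!types %in% labels)) stop("cell type with zero cells")
  cpm <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
  sig <- sapply(types, function(t)
    rowMeans(cpm[, labels == t, drop = FALSE]))
  if (!is.null(genes)) sig <- sig[genes, , drop = FALSE]

  ord <- t(apply(sig, 1, sort, decreasing = TRUE))
  specific <- ord[, 1] >= min_ratio * ord[, 2] & ord[, 1] > 0
  cc <- suppressWarnings(abs(cor(sig)))
  cc[is.na(cc)] <- 0
  dup <- which(upper.tri(diag(ncol(sig))) & cc > 0.999, arr.ind = TRUE)
  if (nrow(dup) > 0)
    warning("near-identical signature columns: ",
            paste(apply(dup, 1, function(i)
              paste(colnames(sig)[i], collapse = "~")), collapse = ", "),
            "; specificity filter drops their distinguishing genes")
  sig <- sig[specific & rowSums(sig) > 0, , drop = FALSE]
  class(sig) <- c("nd_signature", class(sig))
  sig
}

#' @export
print.nd_signature <- function(x, ...) {
  cat("Signature matrix (nd_signature):", nrow(x), "genes x", ncol(x),
      "cell types\n")
  print(utils::head(unclass(x), 4))
  invisible(x)
}
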