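#' Counts per million
#'
#' Scales each sample (column) by 1e6 over its library size. Doubling all
#' counts of a sample leaves its CPM unchanged.
#'
#' @param counts genes x samples non-negative matrix.
#' @return CPM matrix of the same shape.
#' @export
cpm <- function(counts) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size in sample(s): ",
                          paste(which(lib <= 0), collapse = ", "))
  sweep(counts, 2, lib, "/") * 1e6
}

#' Filter bulk genes by the 10/L rule
#'
#' Keeps genes with CPM strictly above \code{10/L} in at least \code{N}
#' samples, where \code{L} is the minimum library size in millions of reads
#' and \code{N} the smallest analysis-group sample size. With L = 20 the
#' threshold is 0.5 CPM.
#'
#' @param cpm_mat genes x samples CPM matrix.
#' @param L minimum library size in millions (> 0).
#' @param N smallest group size (>= 1).
#' @return character vector (or integer indices when unnamed) of kept genes.
#' @export
filter_genes_bulk <- function(cpm_mat, L, N) {
  if (L <= 0) stop("L must be positive")
  if (N < 1) stop("N must be at least 1")
  thr <- 10 / L
  keep <- rowSums(cpm_mat > thr) >= N
  if (is.null(rownames(cpm_mat))) which(keep) else rownames(cpm_mat)[keep]
}

#' Quantile normalization
#'
#' Classic quantile normalization: values are ranked within each sample and
#' replaced by the cross-sample mean of their rank, with ties resolved by
#' averaging tied ranks. After normalization every sample's sorted value
#' vector is identical, and re-applying the transform is a no-op.
#'
#' @param mat genes x samples matrix (typically log2 scale).
#' @return normalized matrix of the same shape.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 samples")
  out <- limma::normalizeQuantiles(mat, ties = TRUE)
  dimnames(out) <- dimnames(mat)
  out
}

#' Normalize a bulk expression matrix
#'
#' RNA-seq counts are converted to log2(CPM + 0.5) and quantile-normalized;
#' microarray intensities are log2(x + 0.5) transformed and
#' quantile-normalized. The result carries the library sizes and a
#' provenance tag.
#'
#' @param bulk an \code{nd_bulk} or genes x samples matrix.
#' @param platform "rnaseq" or "microarray"; taken from \code{nd_bulk} input.
#' @return matrix of class \code{nd_norm} with attributes \code{lib_size}
#'   and \code{platform}.
#' @export
normalize_bulk <- function(bulk, platform = c("rnaseq", "microarray")) {
  if (inherits(bulk, "nd_bulk")) {
    platform <- if (bulk$platform == "microarray") "microarray" else "rnaseq"
    mat <- bulk$counts
  } else {
    platform <- match.arg(platform)
    mat <- as.matrix(bulk)
  }
  lib <- colSums(mat)
  lg <- if (platform == "rnaseq") log2(cpm(mat) + 0.5) else log2(mat + 0.5)
  out <- quantile_normalize(lg)
  attr(out, "lib_size") <- lib
  attr(out, "platform") <- platform
  class(out) <- c("nd_norm", class(out))
  out
}

#' Encode model covariates for a dataset profile
#'
#' Builds the design-ready covariate table for the per-gene linear models.
#' RIN is dichotomized at the profile's cut (high if strictly above, low
#' otherwise; RIN exactly at the cut is low); the RNA-degradation slope is
#' dichotomized at \code{slope_cut} (1 for high). Disease and neuronal
#' proportion are mean-centered to diminish the correlation between their
#' estimated coefficients, and for the AD profile an interaction column is
#' added as the elementwise product of the two centered columns.
#'
#' Profiles and required fields:
#' \describe{
#'   \item{ad_rnaseq}{disease, rin, age, sex, neuronal (default RIN cut 8.5;
#'     use 7.3 for a more leniently collected validation cohort).}
#'   \item{pd_rnaseq}{disease, rin, age, batch, neuronal (default cut 7.8).}
#'   \item{pd_microarray}{disease, age, degradation_slope, neuronal.}
#' }
#'
#' @param metadata data.frame with the profile's required fields (sex coded
#'   1 male / 0 female; disease 1 diseased / 0 control).
#' @param neuronal per-sample neuronal proportion (estimated mRNA share).
#' @param profile dataset profile.
#' @param rin_cut RIN dichotomization cut.
#' @param slope_cut degradation-slope cut (high if strictly above).
#' @return data.frame of model-ready columns, first of which is
#'   \code{disease_c}; attribute \code{profile}.
#' @export
encode_covariates <- function(metadata, neuronal,
                              profile = c("ad_rnaseq", "pd_rnaseq",
                                          "pd_microarray"),
                              rin_cut = NULL, slope_cut = 5) {
  profile <- match.arg(profile)
  required <- switch(profile,
    ad_rnaseq = c("disease", "rin", "age", "sex"),
    pd_rnaseq = c("disease", "rin", "age", "batch"),
    pd_microarray = c("disease", "age", "degradation_slope"))
  missing_f <- setdiff(required, names(metadata))
  if (length(missing_f) > 0)
    stop("missing required metadata field(s): ",
         paste(missing_f, collapse = ", "))
  if (length(neuronal) != nrow(metadata))
    stop("neuronal proportion must align with metadata rows")
  if (is.null(rin_cut))
    rin_cut <- switch(profile, ad_rnaseq = 8.5, pd_rnaseq = 7.8,
                      pd_microarray = NA_real_)

  disease_c <- metadata$disease - mean(metadata$disease)
  neuronal_c <- neuronal - mean(neuronal)
  out <- switch(profile,
    ad_rnaseq = data.frame(
      disease_c = disease_c,
      rin_high = as.integer(metadata$rin > rin_cut),
      neuronal_c = neuronal_c,
      age = metadata$age,
      sex = metadata$sex,
      interaction = disease_c * neuronal_c),
    pd_rnaseq = data.frame(
      disease_c = disease_c,
      rin_high = as.integer(metadata$rin > rin_cut),
      neuronal_c = neuronal_c,
      age = metadata$age,
      batch = as.integer(factor(metadata$batch)) - 1L),
    pd_microarray = data.frame(
      disease_c = disease_c,
      neuronal_c = neuronal_c,
      age = metadata$age,
      degradation = as.integer(metadata$degradation_slope > slope_cut)))
  rownames(out) <- if (!is.null(metadata$sample)) metadata$sample
                   else rownames(metadata)
  attr(out, "profile") <- profile
  out
}

#' PCA-based sample QC
#'
#' SVD-based principal component analysis of the gene-centered expression
#' matrix. Reports the percentage of variance explained per component (sums
#' to 100), Pearson correlations of PC1/PC2 sample scores with neuronal
#' fraction, disease, age and sex (those supplied), Kolmogorov-Smirnov tests
#' of the PC1/PC2 score distributions between arms, and samples whose PC1 or
#' PC2 robust z exceeds \code{z_cut}.
#'
#' @param norm genes x samples normalized matrix.
#' @param metadata optional data.frame with disease/age/sex columns.
#' @param neuronal optional per-sample neuronal fractions.
#' @param z_cut robust-z outlier threshold.
#' @return list of class \code{nd_pcaqc}: \code{scores}, \code{var_explained},
#'   \code{correlations}, \code{ks}, \code{outliers}.
#' @export
pca_qc <- function(norm, metadata = NULL, neuronal = NULL, z_cut = 3) {
  mat <- unclass(norm)
  if (ncol(mat) < 3) stop("need at least 3 samples")
  pr <- prcomp(t(mat), center = TRUE, scale. = FALSE)
  ve <- 100 * pr$sdev^2 / sum(pr$sdev^2)
  sc <- pr$x

  covs <- list()
  if (!is.null(neuronal)) covs$neuronal <- neuronal
  if (!is.null(metadata)) {
    for (f in intersect(c("disease", "age", "sex"), names(metadata)))
      if (length(unique(metadata[[f]])) > 1) covs[[f]] <- metadata[[f]]
  }
  correlations <- if (length(covs) > 0)
    sapply(covs, function(v) c(PC1 = cor(sc[, 1], v), PC2 = cor(sc[, 2], v)))
  else NULL

  ks <- NULL
  if (!is.null(metadata) && "disease" %in% names(metadata) &&
      length(unique(metadata$disease)) == 2) {
    d <- metadata$disease == 1
    ks <- c(PC1 = suppressWarnings(ks.test(sc[d, 1], sc[!d, 1])$p.value),
            PC2 = suppressWarnings(ks.test(sc[d, 2], sc[!d, 2])$p.value))
  }
  rz <- function(x) {
    m <- mad(x)
    if (m == 0) rep(0, length(x)) else abs(x - median(x)) / m
  }
  outliers <- colnames(mat)[rz(sc[, 1]) > z_cut | rz(sc[, 2]) > z_cut]
  structure(list(scores = sc, var_explained = ve,
                 correlations = correlations, ks = ks, outliers = outliers),
            class = "nd_pcaqc")
}

#' Correlation-clustering sample QC
#'
#' Hierarchically clusters samples (average linkage) on Euclidean distances
#' between rows of the sample-sample Pearson correlation matrix, and flags
#' samples whose first merge happens anomalously late (robust z of the first
#' merge height above \code{z_cut}).
#'
#' @param norm genes x samples normalized matrix.
#' @param z_cut robust-z threshold on first-merge heights.
#' @return list with \code{hclust}, \code{first_merge_height},
#'   \code{flagged}.
#' @export
correlation_cluster_qc <- function(norm, z_cut = 3) {
  mat <- unclass(norm)
  if (ncol(mat) < 3) stop("need at least 3 samples")
  cc <- cor(mat)
  h <- hclust(dist(cc), method = "average")
  n <- ncol(mat)
  fm <- rep(NA_real_, n)
  for (i in seq_len(nrow(h$merge))) {
    for (m in h$merge[i, ]) {
      if (m < 0 && is.na(fm[-m])) fm[-m] <- h$height[i]
    }
  }
  med <- median(fm); md <- mad(fm)
  flagged <- if (md == 0) character(0)
             else colnames(mat)[(fm - med) / md > z_cut]
  list(hclust = h,
       first_merge_height = stats::setNames(fm, colnames(mat)),
       flagged = flagged)
}

#' Marker-gene sanity checks
#'
#' Welch two-sample t-tests of each marker gene between diseased and control
#' arms, BH-adjusted within the returned table. Markers absent from the
#' matrix are listed as missing, not an error; markers with zero variance in
#' both arms are reported with NA statistics.
#'
#' @param norm genes x samples normalized matrix.
#' @param metadata data.frame with a \code{disease} column (1/0).
#' @param markers named list of marker gene vectors per cell type.
#' @return list with \code{table} (data.frame: type, gene, mean_diff, t, p,
#'   fdr) and \code{missing}.
#' @export
marker_checks <- function(norm, metadata, markers) {
  mat <- unclass(norm)
  d <- metadata$disease == 1
  rows <- list(); missing <- character(0)
  for (type in names(markers)) {
    for (g in markers[[type]]) {
      if (!g %in% rownames(mat)) { missing <- c(missing, g); next }
      x <- mat[g, d]; y <- mat[g, !d]
      tt <- tryCatch(t.test(x, y), error = function(e) NULL)
      rows[[length(rows) + 1]] <- data.frame(
        type = type, gene = g, mean_diff = mean(x) - mean(y),
        t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
        p = if (is.null(tt)) NA_real_ else tt$p.value,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(tab)) tab$fdr <- p.adjust(tab$p, method = "BH")
  list(table = tab, missing = missing)
}
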