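#' Build a simulation configuration
#'
#' Materialises every generative assumption used by the synthetic-data module:
#' per-gene per-cell-type baseline expression rates, per-cell-type mRNA content,
#' negative-binomial dispersion, the assignment of genes to planted effect
#' classes with their log2 effect sizes, covariate coefficients, per-arm
#' cell-fraction distributions, and the perturbagen panel layout. All
#' downstream simulators are pure functions of the returned configuration and
#' a seed, so planted truth is sufficient to score every pipeline stage.
#'
#' Effect classes:
#' \describe{
#'   \item{composition_driven}{cell-type-specific (marker) genes; their bulk
#'     expression tracks cell composition but carries no disease effect.}
#'   \item{systemic}{genes multiplied by \code{2^(effect * disease)} in every
#'     cell type (the intrinsic disease effect).}
#'   \item{interaction}{genes whose disease effect scales with the (centered)
#'     neuronal mRNA share.}
#'   \item{covariate_only}{genes responding to age/sex/RIN/batch only.}
#'   \item{null}{no planted signal.}
#' }
#'
#' Cohort sizes default to the study design this workflow targets: an AD-like
#' discovery cohort of 71 diseased / 32 control samples with an independent
#' 9 / 23-14 validation cohort, and a PD-like discovery cohort of 15 / 26 with
#' an 8 / 10 male-only microarray-like validation cohort. AD-like diseased
#' arms draw neuronal cell fractions with mean 0.60 vs 0.70 in controls;
#' PD-like arms share one distribution. Neuron mRNA content defaults to 2.0
#' versus 1.0 for glia, so estimated fractions are mRNA shares, not cell
#' counts.
#'
#' @param n_genes number of genes.
#' @param cell_types ordered cell-type labels (ties and column order follow
#'   this order everywhere downstream).
#' @param n_cells_per_type cells per type in the single-cell reference.
#' @param mrna_content per-cell-type relative mRNA content scalar.
#' @param dispersion negative-binomial dispersion (scalar or per-gene vector);
#'   counts are drawn with \code{size = 1/dispersion}, so 0 means Poisson.
#' @param class_fractions named fractions of genes per effect class
#'   (composition_driven, systemic, interaction, covariate_only; remainder is
#'   null).
#' @param systemic_effect absolute log2 effect size of systemic genes
#'   (signs alternate).
#' @param interaction_effect absolute log2-per-unit effect of interaction
#'   genes on the centered disease x centered neuronal-share product.
#' @param marker_fold fold elevation of a marker gene in its own type.
#' @param covariate_effects named log2-per-unit coefficients for age, sex,
#'   rin and batch applied to covariate_only genes.
#' @param composition_concentration Beta concentration of the per-sample
#'   neuronal cell fraction within an arm. The default of 10 reproduces the
#'   broad neuronal-share spread of real degenerating-brain cohorts (95
#'   percent interval of the cell fraction roughly 0.4 to 0.95 at mean 0.7),
#'   wide enough that the low-neuron sample filter occasionally triggers.
#' @param glia_concentration Dirichlet concentration of the split of the
#'   non-neuronal remainder across glial types. The high default makes
#'   neuronal loss the dominant composition axis (glial shares rise roughly
#'   in proportion as neurons are lost), the regime in which a single
#'   neuronal-proportion covariate captures composition.
#' @param ad_fraction_means,pd_fraction_means named lists with per-arm mean
#'   cell-fraction vectors (\code{control}, \code{diseased}).
#' @param cohort_sizes named list per disease of two cohorts, each
#'   \code{c(diseased=, control=)}.
#' @param sc_depth expected counts per reference cell (before mRNA-content
#'   and per-cell library scaling).
#' @param bulk_depth expected library size of bulk RNA-seq samples.
#' @param frac_degenerate fraction of reference cells made deliberately
#'   low-quality (tiny library, inflated mitochondrial load) for QC testing.
#' @param n_mislabeled number of reference cells whose generating type
#'   differs from their label.
#' @param mito_fraction fraction of genes flagged mitochondrial.
#' @param perturbagen list with \code{n_compounds}, \code{n_cell_lines},
#'   \code{n_doses}, \code{n_reversers}, \code{n_mimickers},
#'   \code{n_confounders}, \code{signal}, \code{noise_sd}.
#' @param seed integer seed governing the materialised baseline rates and the
#'   default seed of each simulator.
#' @return an object of class \code{nd_config}.
#' @examples
#' cfg <- sim_config(n_genes = 500, seed = 1)
#' table(cfg$effect_class)
#' @export
sim_config <- function(n_genes = 2000,
                       cell_types = c("astrocyte", "microglia", "neuron",
                                      "oligodendrocyte"),
                       n_cells_per_type = rep(150L, length(cell_types)),
                       mrna_content = stats::setNames(
                         ifelse(cell_types == "neuron", 2.0, 1.0), cell_types),
                       dispersion = 0.05,
                       class_fractions = c(composition_driven = 0.20,
                                           systemic = 0.05,
                                           interaction = 0.03,
                                           covariate_only = 0.05),
                       systemic_effect = 1.0,
                       interaction_effect = 3.0,
                       marker_fold = 8,
                       covariate_effects = c(age = 0.02, sex = 0.5,
                                             rin = -0.3, batch = 0.4),
                       composition_concentration = 10,
                       glia_concentration = 150,
                       ad_fraction_means = list(
                         control  = c(0.15, 0.05, 0.70, 0.10),
                         diseased = c(0.20, 0.07, 0.60, 0.13)),
                       pd_fraction_means = list(
                         control  = c(0.17, 0.06, 0.65, 0.12),
                         diseased = c(0.17, 0.06, 0.65, 0.12)),
                       cohort_sizes = list(
                         ad = list(discovery  = c(diseased = 71, control = 32),
                                   validation = c(diseased = 9,  control = 14)),
                         pd = list(discovery  = c(diseased = 15, control = 26),
                                   validation = c(diseased = 8,  control = 10))),
                       sc_depth = 5e4,
                       bulk_depth = 5e6,
                       frac_degenerate = 0.02,
                       n_mislabeled = 3L,
                       mito_fraction = 0.05,
                       perturbagen = list(n_compounds = 200, n_cell_lines = 3,
                                          n_doses = 2, n_reversers = 2,
                                          n_mimickers = 2, n_confounders = 2,
                                          signal = 2, noise_sd = 0.3),
                       seed = 42L) {
  if (n_genes < 1 || any(n_cells_per_type < 1))
    stop("n_genes and n_cells_per_type must be positive")
  if (length(cell_types) < 2) stop("need at least two cell types")
  if (length(n_cells_per_type) != length(cell_types))
    stop("n_cells_per_type must match cell_types")
  if (any(mrna_content <= 0)) stop("mrna_content must be strictly positive")
  if (any(class_fractions < 0) || sum(class_fractions) > 1)
    stop("class_fractions must be non-negative and sum to at most 1")
  for (fm in c(ad_fraction_means, pd_fraction_means)) {
    if (any(fm < 0) || abs(sum(fm) - 1) > 1e-8)
      stop("fraction means must be non-negative and sum to 1")
  }
  sz <- unlist(cohort_sizes)
  if (any(sz < 1)) stop("cohort sizes must be positive")

  K <- length(cell_types)
  genes <- sprintf("g%05d", seq_len(n_genes))

  cfg <- with_seed(seed, {
    # gene base rates and effect-class assignment
    base <- rlnorm(n_genes, meanlog = 3, sdlog = 1)
    n_comp <- round(class_fractions[["composition_driven"]] * n_genes)
    n_sys  <- round(class_fractions[["systemic"]] * n_genes)
    n_int  <- round(class_fractions[["interaction"]] * n_genes)
    n_cov  <- round(class_fractions[["covariate_only"]] * n_genes)
    cls <- rep("null", n_genes)
    idx <- sample.int(n_genes)
    take <- function(n) { out <- idx[seq_len(n)]; idx <<- idx[-seq_len(n)]; out }
    i_comp <- take(n_comp); i_sys <- take(n_sys)
    i_int <- take(n_int);  i_cov <- take(n_cov)
    cls[i_comp] <- "composition_driven"; cls[i_sys] <- "systemic"
    cls[i_int] <- "interaction";         cls[i_cov] <- "covariate_only"

    # baseline rates: markers elevated marker_fold-fold in their own type
    baseline <- matrix(base, n_genes, K, dimnames = list(genes, cell_types))
    marker_type <- rep(NA_character_, n_genes)
    marker_type[i_comp] <- cell_types[(seq_along(i_comp) - 1) %% K + 1]
    for (t in seq_len(K)) {
      own <- which(marker_type == cell_types[t])
      baseline[own, t] <- baseline[own, t] * marker_fold
    }

    beta_disease <- numeric(n_genes)
    beta_disease[i_sys] <- systemic_effect * rep_len(c(1, -1), n_sys)
    beta_interaction <- numeric(n_genes)
    beta_interaction[i_int] <- interaction_effect * rep_len(c(1, -1), n_int)

    mito <- rep(FALSE, n_genes)
    n_mito <- round(mito_fraction * n_genes)
    mito[sample(which(cls == "null"), n_mito)] <- TRUE

    list(baseline = baseline, effect_class = cls, marker_type = marker_type,
         beta_disease = beta_disease, beta_interaction = beta_interaction,
         mito_flag = mito)
  })

  structure(c(cfg, list(
    n_genes = n_genes, genes = genes, cell_types = cell_types,
    n_cells_per_type = stats::setNames(as.integer(n_cells_per_type), cell_types),
    mrna_content = mrna_content, dispersion = dispersion,
    covariate_effects = covariate_effects,
    composition_concentration = composition_concentration,
    glia_concentration = glia_concentration,
    ad_fraction_means = lapply(ad_fraction_means, stats::setNames, cell_types),
    pd_fraction_means = lapply(pd_fraction_means, stats::setNames, cell_types),
    cohort_sizes = cohort_sizes,
    sc_depth = sc_depth, bulk_depth = bulk_depth,
    frac_degenerate = frac_degenerate, n_mislabeled = as.integer(n_mislabeled),
    perturbagen = perturbagen, seed = as.integer(seed))),
    class = "nd_config")
}

#' @export
print.nd_config <- function(x, ...) {
  cat("Simulation configuration (nd_config)\n")
  cat("  genes:", x$n_genes, " cell types:",
      paste(x$cell_types, collapse = ", "), "\n")
  cat("  effect classes:",
      paste(names(table(x$effect_class)), table(x$effect_class),
            sep = "=", collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
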