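#' Simulate a single-cell reference dataset
#'
#' Draws a genes x cells count matrix in which each cell's counts follow a
#' negative binomial with mean proportional to its generating type's baseline
#' rate, its type's mRNA content, and a lognormal per-cell library scale.
#' A configurable fraction of cells is made deliberately degenerate (tiny
#' library, inflated mitochondrial counts) and a configurable number of cells
#' is mislabeled (generated from one type, annotated as another) so that QC
#' and misclassification detection can be scored against truth.
#'
#' @param config an \code{\link{sim_config}} object.
#' @param seed integer; defaults to \code{config$seed}.
#' @return an object of class \code{nd_reference}: list with \code{counts}
#'   (genes x cells integer matrix), \code{cell_type} (annotated label),
#'   \code{true_type} (generating label), \code{mito_flag},
#'   \code{degenerate}, and \code{true_means} (the baseline rate matrix).
#' @examples
#' ref <- simulate_reference(sim_config(n_genes = 200,
#'   n_cells_per_type = rep(20, 4), seed = 1))
#' dim(ref$counts)
#' @export
simulate_reference <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "nd_config"))
  with_seed(seed, {
    types <- config$cell_types
    labels <- rep(types, config$n_cells_per_type)
    n_cells <- length(labels)
    true_type <- labels
    # planted mislabeled cells: generating type differs from the label
    if (config$n_mislabeled > 0) {
      mis <- sample.int(n_cells, config$n_mislabeled)
      for (i in mis)
        true_type[i] <- sample(setdiff(types, labels[i]), 1)
    }
    degenerate <- runif(n_cells) < config$frac_degenerate
    lib_scale <- rlnorm(n_cells, 0, 0.25)
    lib_scale[degenerate] <- lib_scale[degenerate] * 0.03

    size <- 1 / pmax(config$dispersion, 1e-12)  # NB size; ~Poisson when disp ~ 0
    counts <- matrix(0L, config$n_genes, n_cells,
                     dimnames = list(config$genes,
                                     sprintf("cell%04d", seq_len(n_cells))))
    for (j in seq_len(n_cells)) {
      t <- true_type[j]
      p <- config$baseline[, t] / sum(config$baseline[, t])
      mu <- config$sc_depth * config$mrna_content[[t]] * lib_scale[j] * p
      if (degenerate[j]) mu[config$mito_flag] <- mu[config$mito_flag] * 30
      counts[, j] <- rnbinom(config$n_genes, mu = mu, size = size)
    }
    structure(list(counts = counts, cell_type = labels, true_type = true_type,
                   mito_flag = config$mito_flag, degenerate = degenerate,
                   true_means = config$baseline, cell_types = types),
              class = "nd_reference")
  })
}

#' @export
print.nd_reference <- function(x, ...) {
  cat("Single-cell reference (nd_reference):", nrow(x$counts), "genes x",
      ncol(x$counts), "cells\n")
  print(table(x$cell_type))
  invisible(x)
}

#' Simulate a bulk cohort with known composition and planted effects
#'
#' Each sample's expected expression is the mRNA-content-weighted mixture of
#' the cell-type baseline profiles at that sample's true cell fractions,
#' multiplied by \code{2^eta} where \code{eta} collects the planted log2
#' effects of the gene's class (systemic disease, interaction with the
#' centered neuronal mRNA share, or covariates). AD-like cohorts draw
#' diseased-arm neuronal fractions from a shifted distribution; PD-like
#' cohorts use one distribution for both arms. RNA-seq cohorts yield
#' negative-binomial counts at a lognormal library depth; the PD validation
#' cohort is microarray-like and yields positive intensities with lognormal
#' noise plus an RNA-degradation slope in its metadata. Sex is simulated for
#' AD-like cohorts only (the PD cohorts this emulates were male-only).
#'
#' @param config an \code{\link{sim_config}}.
#' @param reference the matching \code{nd_reference} (carried for provenance;
#'   generation uses the shared baseline rates).
#' @param disease_kind "ad" or "pd".
#' @param cohort "discovery" or "validation".
#' @param seed integer seed.
#' @return an object of class \code{nd_bulk}: \code{counts} (genes x samples),
#'   \code{metadata} (disease, age, sex, rin, batch, degradation_slope),
#'   \code{true_fractions} (cell fractions), \code{true_shares} (mRNA shares),
#'   \code{truth} (per-gene planted coefficients and class),
#'   \code{platform} ("rnaseq" or "microarray").
#' @export
simulate_bulk_cohort <- function(config, reference, disease_kind = c("ad", "pd"),
                                 cohort = c("discovery", "validation"),
                                 seed = config$seed + 1L) {
  stopifnot(inherits(config, "nd_config"))
  disease_kind <- match.arg(disease_kind)
  cohort <- match.arg(cohort)
  with_seed(seed, {
    sizes <- config$cohort_sizes[[disease_kind]][[cohort]]
    n_d <- sizes[["diseased"]]; n_c <- sizes[["control"]]
    n <- n_d + n_c
    disease <- c(rep(1L, n_d), rep(0L, n_c))
    platform <- if (disease_kind == "pd" && cohort == "validation")
      "microarray" else "rnaseq"

    fm <- if (disease_kind == "ad") config$ad_fraction_means
          else config$pd_fraction_means
    conc <- config$composition_concentration
    # hierarchical composition: neuronal fraction ~ Beta (the dominant
    # axis), glial remainder split ~ high-concentration Dirichlet
    draw_fractions <- function(m, k) {
      fn <- stats::rbeta(k, conc * m[["neuron"]],
                         conc * (1 - m[["neuron"]]))
      glia <- setdiff(config$cell_types, "neuron")
      gm <- m[glia] / sum(m[glia])
      gs <- rdirichlet(k, config$glia_concentration * gm) * (1 - fn)
      colnames(gs) <- glia
      out <- cbind(gs, neuron = fn)[, config$cell_types, drop = FALSE]
      colnames(out) <- config$cell_types
      out
    }
    fr <- matrix(NA_real_, n, length(config$cell_types),
                 dimnames = list(sprintf("s%03d", seq_len(n)), config$cell_types))
    fr[disease == 1L, ] <- draw_fractions(fm$diseased, n_d)
    fr[disease == 0L, ] <- draw_fractions(fm$control, n_c)
    m <- config$mrna_content[config$cell_types]
    shares <- sweep(fr, 2, m, "*"); shares <- shares / rowSums(shares)

    age <- round(rnorm(n, 76, 7))
    sex <- if (disease_kind == "ad") rbinom(n, 1, 0.5) else rep(1L, n)
    rin <- round(pmin(10, pmax(5, rnorm(n, 8.6, 0.8))), 1)
    batch <- if (disease_kind == "pd" && platform == "rnaseq")
      sample(c("b1", "b2"), n, replace = TRUE) else rep("b1", n)
    degradation_slope <- if (platform == "microarray")
      round(rnorm(n, 5, 1.5), 2) else rep(NA_real_, n)

    # planted log2 effect per gene x sample
    ce <- config$covariate_effects
    neuro_c <- shares[, "neuron"] - mean(shares[, "neuron"])
    dis_c <- disease - mean(disease)
    eta <- outer(config$beta_disease, disease) +
      outer(config$beta_interaction, dis_c * neuro_c)
    cov_gene <- config$effect_class == "covariate_only"
    cov_eff <- ce[["age"]] * (age - mean(age)) + ce[["sex"]] * sex +
      ce[["rin"]] * (rin - mean(rin)) + ce[["batch"]] * (batch == "b2")
    eta[cov_gene, ] <- eta[cov_gene, ] + rep(cov_eff, each = sum(cov_gene))

    expected <- (config$baseline %*% t(fr * rep(m, each = n))) * 2^eta
    prob <- sweep(expected, 2, colSums(expected), "/")

    if (platform == "rnaseq") {
      depth <- rlnorm(n, log(config$bulk_depth), 0.15)
      size <- 1 / pmax(config$dispersion, 1e-12)
      counts <- matrix(rnbinom(length(prob),
                               mu = prob * rep(depth, each = nrow(prob)),
                               size = size),
                       nrow(prob), n, dimnames = dimnames(prob))
    } else {
      counts <- prob * 1e6 * matrix(rlnorm(length(prob), 0, 0.25),
                                    nrow(prob), n)
      dimnames(counts) <- dimnames(prob)
    }

    truth <- data.frame(gene = config$genes, class = config$effect_class,
                        marker_type = config$marker_type,
                        beta_disease = config$beta_disease,
                        beta_interaction = config$beta_interaction,
                        stringsAsFactors = FALSE)
    metadata <- data.frame(sample = rownames(fr), disease = disease, age = age,
                           sex = sex, rin = rin, batch = batch,
                           degradation_slope = degradation_slope,
                           stringsAsFactors = FALSE)
    structure(list(counts = counts, metadata = metadata, true_fractions = fr,
                   true_shares = shares, truth = truth, platform = platform,
                   disease_kind = disease_kind, cohort = cohort),
              class = "nd_bulk")
  })
}

#' @export
print.nd_bulk <- function(x, ...) {
  cat("Bulk cohort (nd_bulk):", nrow(x$counts), "genes x", ncol(x$counts),
      "samples;", x$disease_kind, x$cohort, sprintf("[%s]\n", x$platform))
  cat("  diseased:", sum(x$metadata$disease == 1),
      " control:", sum(x$metadata$disease == 0), "\n")
  invisible(x)
}

#' Simulate artificial mixtures from a single-cell reference
#'
#' Count-level emulation of chimeric read sampling: all reference cells of a
#' type are pooled into one per-type count profile; each mixture allocates
#' \code{depth} total counts to types multinomially at its proportion row and
#' distributes each type's counts across genes multinomially at the pooled
#' profile. Total counts per mixture equal \code{depth} exactly.
#'
#' @param reference an \code{nd_reference}.
#' @param proportions mixtures x cell-types matrix; rows must lie on the
#'   simplex (sum to 1 within 1e-8, entries non-negative).
#' @param depth total counts per mixture.
#' @param seed integer seed.
#' @return an \code{nd_bulk}-like object with \code{counts},
#'   \code{true_fractions} (the read/mRNA proportions), platform "mixture".
#' @export
simulate_mixtures <- function(reference, proportions, depth = 3.5e5,
                              seed = 7L) {
  stopifnot(inherits(reference, "nd_reference"))
  proportions <- as.matrix(proportions)
  if (is.null(colnames(proportions)))
    colnames(proportions) <- reference$cell_types
  if (any(proportions < 0) || any(abs(rowSums(proportions) - 1) > 1e-8))
    stop("proportion rows must be non-negative and sum to 1 within 1e-8")
  if (depth <= 0) stop("depth must be positive")
  with_seed(seed, {
    types <- colnames(proportions)
    pools <- sapply(types, function(t)
      rowSums(reference$counts[, reference$cell_type == t, drop = FALSE]))
    pool_p <- sweep(pools, 2, colSums(pools), "/")
    n_mix <- nrow(proportions)
    counts <- matrix(0L, nrow(pool_p), n_mix,
                     dimnames = list(rownames(pool_p),
                                     sprintf("mix%03d", seq_len(n_mix))))
    for (i in seq_len(n_mix)) {
      per_type <- as.vector(rmultinom(1, depth, proportions[i, ]))
      for (t in seq_along(types)) {
        if (per_type[t] > 0)
          counts[, i] <- counts[, i] +
            as.vector(rmultinom(1, per_type[t], pool_p[, t]))
      }
    }
    rownames(proportions) <- colnames(counts)
    structure(list(counts = counts, true_fractions = proportions,
                   metadata = data.frame(sample = colnames(counts)),
                   platform = "mixture"),
              class = "nd_bulk")
  })
}

#' Simulate a perturbagen panel (CMap-style z-score matrix)
#'
#' Builds a genes x conditions perturbation z-score matrix with planted
#' compound roles: reversers anti-track the disease score vector
#' (\code{z = -signal * scale(score) + noise}), mimickers track it,
#' neuronal confounders track a mixture dominated by the disease scores but
#' with a substantial neuronal-score component, and neutral compounds are
#' independent noise. The first planted reverser is noise-free. Each compound
#' is replicated across the configured cell lines and doses. Planted
#' compounds are given "launched" clinical status; neutral compounds draw a
#' status at random.
#'
#' @param config an \code{\link{sim_config}} (uses \code{config$perturbagen}).
#' @param disease_scores named numeric vector (>= 100 genes).
#' @param neuronal_scores named numeric vector on the same genes; generated
#'   at random if missing.
#' @param seed integer seed.
#' @return object of class \code{nd_panel}: \code{zscores} (genes x
#'   conditions), \code{conditions} (compound, cell_line, dose, time,
#'   plate, status), \code{planted_roles} (named vector per compound).
#' @export
simulate_perturbagens <- function(config, disease_scores,
                                  neuronal_scores = NULL,
                                  seed = config$seed + 2L) {
  stopifnot(inherits(config, "nd_config"))
  if (length(disease_scores) < 100)
    stop("disease_scores must cover at least 100 genes")
  if (is.null(names(disease_scores)))
    stop("disease_scores must be named by gene")
  ps <- config$perturbagen
  with_seed(seed, {
    genes <- names(disease_scores)
    if (is.null(neuronal_scores))
      neuronal_scores <- stats::setNames(rnorm(length(genes)), genes)
    neuronal_scores <- neuronal_scores[genes]
    zd <- as.vector(scale(disease_scores))
    zn <- as.vector(scale(neuronal_scores))

    n_cmp <- ps$n_compounds
    roles <- rep("neutral", n_cmp)
    roles[seq_len(ps$n_reversers)] <- "reverser"
    roles[ps$n_reversers + seq_len(ps$n_mimickers)] <- "mimicker"
    roles[ps$n_reversers + ps$n_mimickers + seq_len(ps$n_confounders)] <-
      "neuronal_confounder"
    compounds <- sprintf("cmpd%03d", seq_len(n_cmp))
    names(roles) <- compounds
    status <- ifelse(roles == "neutral",
                     sample(c("launched", "clinical", "preclinical"), n_cmp,
                            replace = TRUE, prob = c(0.4, 0.3, 0.3)),
                     "launched")

    cell_lines <- sprintf("CL%d", seq_len(ps$n_cell_lines))
    doses <- sprintf("%gum", 10^(seq_len(ps$n_doses) - 1))
    conditions <- expand.grid(compound = compounds, cell_line = cell_lines,
                              dose = doses, stringsAsFactors = FALSE)
    conditions$time <- "24h"
    conditions$plate <- "CPD"
    conditions$status <- status[conditions$compound]
    conditions$condition <- sprintf("%s_%s_%s", conditions$compound,
                                    conditions$cell_line, conditions$dose)

    G <- length(genes)
    z <- matrix(NA_real_, G, nrow(conditions),
                dimnames = list(genes, conditions$condition))
    first_reverser <- compounds[1]
    for (j in seq_len(nrow(conditions))) {
      cmp <- conditions$compound[j]
      noise <- if (cmp == first_reverser) 0 else ps$noise_sd
      mu <- switch(roles[[cmp]],
        reverser = -ps$signal * zd,
        mimicker = ps$signal * zd,
        neuronal_confounder = ps$signal * (-0.85 * zd + 0.4 * zn),
        neutral = 0)
      z[, j] <- mu + rnorm(G, 0, max(noise, if (roles[[cmp]] == "neutral") 1 else 0))
    }
    structure(list(zscores = z, conditions = conditions,
                   planted_roles = roles),
              class = "nd_panel")
  })
}

#' @export
print.nd_panel <- function(x, ...) {
  cat("Perturbagen panel (nd_panel):", nrow(x$zscores), "genes x",
      ncol(x$zscores), "conditions;",
      length(unique(x$conditions$compound)), "compounds\n")
  print(table(x$planted_roles))
  invisible(x)
}
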