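#' Build a pipeline configuration
#'
#' Collects the simulation configuration, stage toggles, thresholds and
#' permutation counts for \code{\link{run_pipeline}}. Defaults are the
#' desk-scale study conditions of the synthetic generator.
#'
#' @param sim an \code{\link{sim_config}}.
#' @param out_dir output directory (created if needed).
#' @param stages named logical toggles: deconvolution, diffexp, consistency,
#'   concordance, gsea, drug_screen.
#' @param fdr_cut,fdr_cut_microarray differential-expression FDR thresholds.
#' @param neuron_threshold low-neuron sample filter cut.
#' @param confound_cut drug-screen neuronal-confound cut.
#' @param k candidates per direction in the drug screen.
#' @param n_perm_consistency,n_perm_concordance,n_perm_gsea permutation
#'   counts.
#' @param deconv_method "nnls" or "nusvr".
#' @param seed master seed.
#' @return list of class \code{nd_pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(),
                            out_dir = tempfile("nd_run_"),
                            stages = c(deconvolution = TRUE, diffexp = TRUE,
                                       consistency = TRUE,
                                       concordance = TRUE, gsea = TRUE,
                                       drug_screen = TRUE),
                            fdr_cut = 0.05, fdr_cut_microarray = 0.11,
                            neuron_threshold = 0.40, confound_cut = 0.05,
                            k = 20, n_perm_consistency = 200,
                            n_perm_concordance = 1e4, n_perm_gsea = 500,
                            deconv_method = "nnls", seed = 1L) {
  structure(list(sim = sim, out_dir = out_dir, stages = stages,
                 fdr_cut = fdr_cut, fdr_cut_microarray = fdr_cut_microarray,
                 neuron_threshold = neuron_threshold,
                 confound_cut = confound_cut, k = k,
                 n_perm_consistency = n_perm_consistency,
                 n_perm_concordance = n_perm_concordance,
                 n_perm_gsea = n_perm_gsea, deconv_method = deconv_method,
                 seed = as.integer(seed)),
            class = "nd_pipeline_config")
}

# Internal: per-cohort prep -> deconvolution -> model fit -> moderation.
run_cohort <- function(bulk, config, sig) {
  est <- estimate_composition(bulk, sig, method = config$deconv_method)
  policy <- if (ncol(bulk$counts) < 12) "keep" else "remove"
  flt <- filter_low_neuron_samples(est, threshold = config$neuron_threshold,
                                   policy = policy)
  keep <- flt$kept
  counts <- bulk$counts[, keep, drop = FALSE]
  meta <- bulk$metadata[bulk$metadata$sample %in% keep, , drop = FALSE]
  neuronal <- est$fractions[keep, "neuron"]

  norm <- normalize_bulk(structure(list(counts = counts,
                                        platform = bulk$platform),
                                   class = "nd_bulk"))
  if (bulk$platform == "rnaseq") {
    lmill <- min(attr(norm, "lib_size")) / 1e6
    nmin <- min(table(meta$disease))
    keep_g <- filter_genes_bulk(cpm(counts), L = lmill, N = nmin)
    norm <- norm[keep_g, , drop = FALSE]
  }
  profile <- if (bulk$disease_kind == "ad") "ad_rnaseq"
             else if (bulk$platform == "microarray") "pd_microarray"
             else "pd_rnaseq"
  cov <- encode_covariates(meta, neuronal, profile = profile)
  eff <- moderate(fit_models(norm, cov))
  list(est = est, filter_log = flt$log, norm = norm, cov = cov, eff = eff,
       meta = meta, profile = profile)
}

#' Run the full synthetic-data analysis pipeline
#'
#' Executes, in order: reference simulation, single-cell QC and gene
#' filtering, variance decomposition, signature construction, simulation of
#' two cohorts per disease, deconvolution with the low-neuron sample filter,
#' normalization and per-gene linear modeling with moderated statistics,
#' cross-dataset consistency (t-product permutation FDR and combined
#' scores) per disease, cross-disease concordance, GSEA on the combined
#' scores, and the perturbagen reversal screen. Outputs are written as TSV
#' under \code{config$out_dir} together with a run manifest carrying the
#' seed and a configuration hash. A stage failure aborts with the stage
#' name; outputs written so far are renamed with a \code{.partial} suffix.
#'
#' @param config an \code{\link{pipeline_config}}.
#' @return invisible list with every stage's in-memory results.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "nd_pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(config[setdiff(names(config), "out_dir")])
  written <- character(0)
  emit <- function(writer, name) {
    path <- file.path(config$out_dir, name)
    writer(path)
    header <- sprintf("# seed=%d config=%s", config$seed, cfg_hash)
    body <- readLines(path)
    writeLines(c(header, body), path)
    written <<- c(written, path)
  }
  stage <- "init"
  res <- list()
  tryCatch({
    sim <- config$sim
    stage <- "simulate"
    ref <- simulate_reference(sim)

    stage <- "scqc"
    qc <- compute_cell_qc(ref)
    kept_cells <- filter_cells(qc)$kept
    ref_f <- ref
    ref_f$counts <- ref$counts[, kept_cells, drop = FALSE]
    ref_f$cell_type <- ref$cell_type[kept_cells]
    ref_f$true_type <- ref$true_type[kept_cells]
    ref_f$degenerate <- ref$degenerate[kept_cells]
    keep_g <- filter_genes_sc(ref_f)
    emit(function(p) write.table(qc, p, sep = "\t", quote = FALSE,
                                 row.names = FALSE), "cell_qc.tsv")

    stage <- "signature"
    vd <- decompose_variance(ref_f, genes = keep_g)
    retained <- rownames(vd)[vd$retain]
    mis <- nsc_classify(ref_f)$misclassified
    good <- !colnames(ref_f$counts) %in% mis$cell
    sig <- build_signature(ref_f$counts[, good, drop = FALSE],
                           ref_f$cell_type[good], genes = retained)
    res$signature <- sig
    emit(function(p) write_tsv_matrix(sig, p), "signature.tsv")

    cohorts <- list()
    for (dk in c("ad", "pd")) for (ch in c("discovery", "validation")) {
      stage <- paste0("simulate_bulk_", dk, "_", ch)
      off <- match(paste(dk, ch), c("ad discovery", "ad validation",
                                    "pd discovery", "pd validation"))
      cohorts[[paste(dk, ch, sep = "_")]] <-
        simulate_bulk_cohort(sim, ref, dk, ch, seed = sim$seed + 10L + off)
    }
    res$cohorts <- cohorts

    if (config$stages[["deconvolution"]] || config$stages[["diffexp"]]) {
      stage <- "deconvolution/diffexp"
      fits <- lapply(cohorts, run_cohort, config = config, sig = sig)
      res$fits <- fits
      for (nm in names(fits)) {
        emit(function(p) write_tsv_matrix(fits[[nm]]$est$fractions, p,
                                          id_col = "sample"),
             paste0("fractions_", nm, ".tsv"))
        emit(function(p) write_tsv_matrix(fits[[nm]]$eff$t, p),
             paste0("moderated_t_", nm, ".tsv"))
      }
    }

    scores <- list()
    if (config$stages[["consistency"]]) {
      for (dk in c("ad", "pd")) {
        stage <- paste0("consistency_", dk)
        f1 <- res$fits[[paste0(dk, "_discovery")]]
        f2 <- res$fits[[paste0(dk, "_validation")]]
        cons <- t_product_fdr(f1$norm, f1$cov, f2$norm, f2$cov,
                              n_perm = config$n_perm_consistency,
                              seed = config$seed + 100L)
        cons$score <- combined_score(cons$t1, cons$t2, cons$fdr)
        res[[paste0("consistency_", dk)]] <- cons
        scores[[dk]] <- stats::setNames(cons$score, cons$gene)
        emit(function(p) write.table(cons, p, sep = "\t", quote = FALSE,
                                     row.names = FALSE),
             paste0("consistency_", dk, ".tsv"))
      }
    }

    if (config$stages[["concordance"]] && length(scores) == 2) {
      stage <- "concordance"
      conc <- cross_disease_fdr(scores$ad, scores$pd,
                                n_perm = config$n_perm_concordance,
                                seed = config$seed + 200L)
      res$concordance <- conc
      emit(function(p) write.table(conc, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "concordance.tsv")
    }

    if (config$stages[["gsea"]] && length(scores) == 2) {
      stage <- "gsea"
      common <- stats::setNames(res$concordance$s1 * 0 +
                                  pmin(abs(res$concordance$s1),
                                       abs(res$concordance$s2)) *
                                  sign(res$concordance$s1) *
                                  (sign(res$concordance$s1) ==
                                     sign(res$concordance$s2)),
                                res$concordance$gene)
      truth <- cohorts$ad_discovery$truth
      sets <- list(
        systemic_up = truth$gene[truth$beta_disease > 0],
        systemic_down = truth$gene[truth$beta_disease < 0],
        neuron_markers = truth$gene[!is.na(truth$marker_type) &
                                      truth$marker_type == "neuron"])
      g <- gsea(scores$ad, sets, n_perm = config$n_perm_gsea,
                seed = config$seed + 300L)
      res$gsea <- g
      res$common_scores <- common
      emit(function(p) write.table(g, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "gsea.tsv")
    }

    if (config$stages[["drug_screen"]] && length(scores) == 2) {
      stage <- "drug_screen"
      ad_eff <- res$fits$ad_discovery$eff
      neuro_scores <- stats::setNames(ad_eff$t[, "neuronal_c"],
                                      rownames(ad_eff$t))
      panel <- simulate_perturbagens(sim, scores$ad, neuro_scores,
                                     seed = config$seed + 400L)
      tab <- compound_correlations(panel, scores$ad, neuro_scores)
      cand <- select_candidates(tab, k = config$k,
                                confound_cut = config$confound_cut)
      res$panel <- panel
      res$candidates <- cand
      emit(function(p) write.table(cand, p, sep = "\t", quote = FALSE,
                                   row.names = FALSE), "candidates.tsv")
    }

    stage <- "manifest"
    manifest <- c(sprintf("package: neurodecon %s",
                          as.character(utils::packageVersion("neurodecon"))),
                  sprintf("seed: %d", config$seed),
                  sprintf("config_hash: %s", cfg_hash),
                  sprintf("written: %s", paste(basename(written),
                                               collapse = ", ")))
    writeLines(manifest, file.path(config$out_dir, "manifest.txt"))
    res$manifest <- manifest
    res$out_dir <- config$out_dir
    invisible(res)
  }, error = function(e) {
    for (p in written) file.rename(p, paste0(p, ".partial"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}
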