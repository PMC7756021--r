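# Internal: condition -> cell line -> compound averaging hierarchy.
# Doses/times within a cell line are averaged first, then cell lines.
aggregate_rho <- function(conditions, rho) {
  by_cl <- stats::aggregate(rho,
    by = list(compound = conditions$compound,
              cell_line = conditions$cell_line), FUN = mean)
  by_cmp <- stats::aggregate(by_cl$x, by = list(compound = by_cl$compound),
                             FUN = mean)
  stats::setNames(by_cmp$x, by_cmp$compound)
}

#' Correlate perturbagen signatures with disease-effect scores
#'
#' Computes, over the genes shared between the panel and the score vectors,
#' the Spearman correlation of every condition's perturbation z-scores with
#' the disease-effect scores and with the neuronal-proportion scores.
#' Correlations are averaged hierarchically: doses/times within a cell line
#' first, then cell lines within a compound. For the neuronal scores the
#' absolute correlation is taken per condition before averaging (the
#' stricter reading of the confound filter).
#'
#' @param panel an \code{nd_panel} (or genes x conditions z-score matrix
#'   plus a \code{conditions} data.frame).
#' @param disease_scores named per-gene disease-effect scores.
#' @param neuronal_scores named per-gene neuronal-proportion scores.
#' @param conditions condition metadata when \code{panel} is a bare matrix.
#' @return object of class \code{nd_drugtable}: \code{conditions}
#'   (per-condition rho), \code{compounds} (compound, status, rho_disease,
#'   rho_neuronal_abs), \code{shared_genes}.
#' @export
compound_correlations <- function(panel, disease_scores, neuronal_scores,
                                  conditions = NULL) {
  if (inherits(panel, "nd_panel")) {
    z <- panel$zscores; conditions <- panel$conditions
  } else {
    z <- as.matrix(panel)
    if (is.null(conditions)) stop("conditions metadata required")
  }
  shared <- Reduce(intersect, list(rownames(z), names(disease_scores),
                                   names(neuronal_scores)))
  if (length(shared) < 30)
    stop("fewer than 30 genes shared between panel and score vectors")
  z <- z[shared, , drop = FALSE]
  d <- disease_scores[shared]; nv <- neuronal_scores[shared]

  rho_d <- suppressWarnings(as.vector(cor(z, d, method = "spearman")))
  rho_n <- suppressWarnings(as.vector(cor(z, nv, method = "spearman")))
  cond <- conditions
  cond$rho_disease <- rho_d
  cond$rho_neuronal <- rho_n

  cmp_d <- aggregate_rho(cond, rho_d)
  cmp_n <- aggregate_rho(cond, abs(rho_n))
  status <- cond$status[!duplicated(cond$compound)]
  names(status) <- cond$compound[!duplicated(cond$compound)]
  compounds <- data.frame(compound = names(cmp_d),
                          status = unname(status[names(cmp_d)]),
                          rho_disease = unname(cmp_d),
                          rho_neuronal_abs = unname(cmp_n[names(cmp_d)]),
                          row.names = NULL, stringsAsFactors = FALSE)
  structure(list(conditions = cond, compounds = compounds,
                 shared_genes = shared),
            class = "nd_drugtable")
}

#' @export
print.nd_drugtable <- function(x, ...) {
  cat("Drug-screen correlation table (nd_drugtable):",
      nrow(x$compounds), "compounds,", nrow(x$conditions), "conditions,",
      length(x$shared_genes), "shared genes\n")
  invisible(x)
}

#' Select reversal and induction candidate compounds
#'
#' Restricts to compounds in clinical trials or launched, excludes compounds
#' whose average absolute Spearman correlation with the neuronal-proportion
#' scores reaches \code{confound_cut} (a compound passes only when strictly
#' below the cut), then takes the \code{k} most negative average disease
#' correlations (among strictly negative ones) as reversal candidates and
#' the \code{k} most positive (among strictly positive ones) as induction
#' candidates. Ties are broken by compound id; the two candidate sets are
#' disjoint. When fewer than \code{k} compounds are eligible, all are
#' returned and the shortfall is noted.
#'
#' @param table an \code{nd_drugtable}.
#' @param k candidates per direction.
#' @param confound_cut neuronal-confound threshold (strict <).
#' @param statuses clinical statuses eligible for selection.
#' @return data.frame of class \code{nd_candidates}: compound, status,
#'   rho_disease, rho_neuronal_abs, verdict in \{reversal_candidate,
#'   induction_candidate, excluded_confounded, not_selected\}.
#' @export
select_candidates <- function(table, k = 20, confound_cut = 0.05,
                              statuses = c("clinical", "launched")) {
  stopifnot(inherits(table, "nd_drugtable"))
  tab <- table$compounds
  verdict <- rep("not_selected", nrow(tab))
  confounded <- tab$rho_neuronal_abs >= confound_cut
  verdict[confounded] <- "excluded_confounded"
  eligible <- which(!confounded & tab$status %in% statuses)
  if (length(eligible) < 2 * k)
    message("only ", length(eligible), " eligible compounds for 2x", k,
            " selections")
  ord <- eligible[order(tab$rho_disease[eligible], tab$compound[eligible])]
  rev_idx <- utils::head(ord[tab$rho_disease[ord] < 0], k)
  ind_idx <- utils::head(rev(ord[tab$rho_disease[ord] > 0]), k)
  verdict[rev_idx] <- "reversal_candidate"
  verdict[ind_idx] <- "induction_candidate"
  out <- cbind(tab, verdict = verdict, stringsAsFactors = FALSE)
  class(out) <- c("nd_candidates", "data.frame")
  out
}

#' Joint AD-PD drug map
#'
#' For compounds present in both diseases' correlation tables, reports the
#' per-compound average disease correlations for each disease together with
#' the correlation against a common (cross-disease) score vector, ranked by
#' the latter so the most negative compounds are joint reversal candidates.
#' Compounds missing from either table are excluded and listed in the
#' \code{missing} attribute.
#'
#' @param panel the \code{nd_panel} supplying z-scores for the common-score
#'   correlation.
#' @param table_ad,table_pd \code{nd_drugtable}s for the two diseases.
#' @param common_scores named per-gene common AD-PD score vector.
#' @return data.frame: compound, rho_ad, rho_pd, rho_common (sorted by
#'   rho_common ascending).
#' @export
cross_disease_drug_map <- function(panel, table_ad, table_pd, common_scores) {
  shared_cmp <- intersect(table_ad$compounds$compound,
                          table_pd$compounds$compound)
  missing <- union(setdiff(table_ad$compounds$compound, shared_cmp),
                   setdiff(table_pd$compounds$compound, shared_cmp))
  z <- if (inherits(panel, "nd_panel")) panel$zscores else as.matrix(panel)
  conditions <- if (inherits(panel, "nd_panel")) panel$conditions
                else stop("panel must be an nd_panel")
  shared_g <- intersect(rownames(z), names(common_scores))
  rho_c_cond <- suppressWarnings(as.vector(
    cor(z[shared_g, , drop = FALSE], common_scores[shared_g],
        method = "spearman")))
  rho_c <- aggregate_rho(conditions, rho_c_cond)

  ad <- stats::setNames(table_ad$compounds$rho_disease,
                        table_ad$compounds$compound)
  pd <- stats::setNames(table_pd$compounds$rho_disease,
                        table_pd$compounds$compound)
  out <- data.frame(compound = shared_cmp,
                    rho_ad = unname(ad[shared_cmp]),
                    rho_pd = unname(pd[shared_cmp]),
                    rho_common = unname(rho_c[shared_cmp]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$rho_common, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}
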