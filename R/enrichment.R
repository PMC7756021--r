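#' Read a GMT gene-set file
#'
#' Tab-delimited: set name, description, then member genes.
#'
#' @param path file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  sets
}

#' Write a GMT gene-set file
#'
#' @param sets named list of gene vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, description, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
}

# Internal: weighted KS running-sum enrichment score.
# ord_stat: statistic sorted in ranking order; hit: logical in same order.
running_es <- function(ord_stat, hit, weight) {
  w <- abs(ord_stat)^weight
  wh <- w * hit
  sw <- sum(wh)
  if (sw == 0) return(0)
  n_miss <- sum(!hit)
  if (n_miss == 0) return(1)
  dev <- cumsum(wh) / sw - cumsum(!hit) / n_miss
  dev[which.max(abs(dev))]
}

#' Gene-set enrichment analysis on a per-gene statistic
#'
#' Ranks the universe by the statistic (descending; ties broken by gene
#' identifier for a stable order) and computes the weighted
#' Kolmogorov-Smirnov running-sum enrichment score of each set, with hit
#' increments proportional to |stat|^weight. Significance is assessed by
#' gene-label permutation (equivalently, random sets of the same size; null
#' distributions are shared across sets of equal size): \code{p_up} is the
#' positive-tail and \code{p_down} the negative-tail permutation p-value,
#' each on the grid \{1/(n_perm+1), ...\}, BH-adjusted across sets within
#' each direction. Sets empty after intersection with the universe are
#' dropped and listed in the \code{dropped} attribute. With
#' \code{weight = 0} the score reduces to the classical KS statistic and is
#' invariant to monotone transforms of the statistic.
#'
#' @param stat named per-gene statistic (moderated t, B, or combined score;
#'   must be finite).
#' @param sets named list of gene-identifier vectors.
#' @param n_perm permutations per set size.
#' @param weight exponent on |stat| (1 = classic weighted GSEA).
#' @param seed permutation seed.
#' @return data.frame of class \code{nd_gsea}: set, size, es, p_up, p_down,
#'   fdr_up, fdr_down; attribute \code{dropped}.
#' @export
gsea <- function(stat, sets, n_perm = 1000, weight = 1, seed = 1L) {
  if (length(stat) < 2) stop("universe must contain at least 2 genes")
  if (any(!is.finite(stat))) stop("statistic must be finite")
  if (is.null(names(stat))) stop("stat must be named by gene")
  ord <- order(-stat, names(stat))
  s <- stat[ord]
  universe <- names(s)
  n <- length(universe)

  sets2 <- lapply(sets, intersect, universe)
  dropped <- names(sets2)[lengths(sets2) == 0]
  sets2 <- sets2[lengths(sets2) > 0]

  es <- vapply(sets2, function(gs)
    running_es(s, universe %in% gs, weight), numeric(1))
  sizes <- lengths(sets2)

  null_by_size <- with_seed(seed, {
    out <- list()
    for (k in sort(unique(sizes))) {
      out[[as.character(k)]] <- vapply(seq_len(n_perm), function(b) {
        hit <- logical(n)
        hit[sample.int(n, k)] <- TRUE
        running_es(s, hit, weight)
      }, numeric(1))
    }
    out
  })
  p_up <- p_down <- numeric(length(sets2))
  for (i in seq_along(sets2)) {
    null <- null_by_size[[as.character(sizes[i])]]
    p_up[i] <- (1 + sum(null >= es[i])) / (1 + n_perm)
    p_down[i] <- (1 + sum(null <= es[i])) / (1 + n_perm)
  }
  out <- data.frame(set = names(sets2), size = sizes, es = es,
                    p_up = p_up, p_down = p_down,
                    fdr_up = p.adjust(p_up, method = "BH"),
                    fdr_down = p.adjust(p_down, method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dropped") <- dropped
  class(out) <- c("nd_gsea", "data.frame")
  out
}
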