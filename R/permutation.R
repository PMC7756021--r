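# Internal: disease-coefficient moderated t for one cohort given a covariate
# table; used for both the observed statistic and the permutation null.
disease_tstat <- function(norm, covariates, coef = "disease_c") {
  eff <- moderate(fit_models(norm, covariates))
  eff$t[, coef]
}

# Internal: shuffle the (centered) disease column of a covariate table,
# recomputing the interaction column when present.
shuffle_disease <- function(covariates, perm) {
  cv <- covariates
  cv$disease_c <- covariates$disease_c[perm]
  if ("interaction" %in% names(cv))
    cv$interaction <- cv$disease_c * cv$neuronal_c
  cv
}

#' Cross-dataset consistency by permutation of t-statistic products
#'
#' For each shared gene, the observed statistic is the product of the
#' disease-coefficient moderated t in the two cohorts. The null is built by
#' independently shuffling the disease labels within each cohort (other
#' covariate values stay attached to their samples), refitting, and
#' re-moderating; each gene is compared to its own permutation distribution.
#' By default "more extreme" means larger in absolute value, which keeps the
#' null FDR<0.05 call rate at its nominal level; \code{directional = TRUE}
#' switches to the sign-directional rule (null >= observed when the observed
#' product is non-negative, null <= observed otherwise), which rewards only
#' sign-consistent products but doubles the null call rate. Contradictory
#' genes are zeroed downstream by \code{\link{combined_score}} either way.
#' The per-gene FDR is the proportion of null products more extreme than the
#' observed one, on the grid \{0, 1/n_perm, ..., 1\}.
#'
#' @param norm1,norm2 genes x samples normalized matrices of the two cohorts.
#' @param cov1,cov2 covariate tables from \code{\link{encode_covariates}}.
#' @param n_perm number of permutations (default 5000; below 100 the
#'   resolution is poor and a warning is given; below 1 is an error).
#' @param seed permutation seed. Each cohort's permutation stream is derived
#'   from \code{seed} and a hash of the cohort's expression matrix, so the
#'   result is exactly invariant to relabeling which cohort is "1" or "2".
#' @param directional use the sign-directional extremeness rule instead of
#'   absolute-value extremeness.
#' @param coef name of the disease column.
#' @param exhaustive enumerate every distinct disease-label assignment in
#'   each cohort and cross all pairs instead of Monte-Carlo sampling
#'   (feasible for small cohorts only; \code{n_perm} is then ignored).
#' @return data.frame of class \code{nd_consistency}: gene, t1, t2, product,
#'   fdr; attribute \code{n_null} gives the null size.
#' @export
t_product_fdr <- function(norm1, cov1, norm2, cov2, n_perm = 5000,
                          seed = 1L, directional = FALSE,
                          coef = "disease_c", exhaustive = FALSE) {
  if (!exhaustive) {
    if (n_perm < 1) stop("n_perm must be at least 1")
    if (n_perm < 100) warning("fewer than 100 permutations: FDR resolution ",
                              "is only 1/", n_perm)
  }
  shared <- intersect(rownames(norm1), rownames(norm2))
  if (length(shared) < 10) stop("fewer than 10 shared genes")
  y1 <- unclass(norm1)[shared, , drop = FALSE]
  y2 <- unclass(norm2)[shared, , drop = FALSE]
  t1 <- disease_tstat(y1, cov1, coef)
  t2 <- disease_tstat(y2, cov2, coef)
  obs <- t1 * t2
  more_extreme <- function(nullp) {
    if (directional) ifelse(obs >= 0, nullp >= obs, nullp <= obs)
    else abs(nullp) >= abs(obs)
  }
  count <- numeric(length(shared))

  if (exhaustive) {
    # all distinct arrangements of each cohort's disease labels
    tmat <- function(y, cv) {
      d <- cv[[coef]]
      n_pos <- sum(d == max(d))
      pos_sets <- utils::combn(nrow(cv), n_pos)
      apply(pos_sets, 2, function(ix) {
        p <- integer(nrow(cv))
        p[ix] <- which(d == max(d))
        p[-ix] <- which(d != max(d))
        disease_tstat(y, shuffle_disease(cv, p), coef)
      })
    }
    tm1 <- tmat(y1, cov1); tm2 <- tmat(y2, cov2)
    n_null <- ncol(tm1) * ncol(tm2)
    for (i in seq_len(ncol(tm1))) for (j in seq_len(ncol(tm2)))
      count <- count + more_extreme(tm1[, i] * tm2[, j])
  } else {
    n1 <- nrow(cov1); n2 <- nrow(cov2)
    cohort_seed <- function(y) {
      h <- strtoi(substr(rlang::hash(unname(y)), 1, 7), base = 16L)
      (abs(seed) + h) %% 2147483629L
    }
    perms1 <- with_seed(cohort_seed(y1),
                        replicate(n_perm, sample.int(n1)))
    perms2 <- with_seed(cohort_seed(y2),
                        replicate(n_perm, sample.int(n2)))
    n_null <- n_perm
    for (b in seq_len(n_perm)) {
      p1 <- disease_tstat(y1, shuffle_disease(cov1, perms1[, b]), coef)
      p2 <- disease_tstat(y2, shuffle_disease(cov2, perms2[, b]), coef)
      count <- count + more_extreme(p1 * p2)
    }
  }
  out <- data.frame(gene = shared, t1 = t1, t2 = t2, product = obs,
                    fdr = count / n_null, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "n_null") <- n_null
  class(out) <- c("nd_consistency", "data.frame")
  out
}

#' Combined cross-dataset score
#'
#' Signed log-FDR score: \code{-log10(max(fdr, floor))} when both
#' t-statistics are positive, \code{log10(max(fdr, floor))} when both are
#' negative, and 0 when the signs are contradictory. The default floor of
#' 1e-5 (half the resolution of a 5000-permutation FDR) keeps zero FDRs
#' finite, bounding |score| by 5.
#'
#' @param t1,t2 disease-coefficient t-statistics in the two cohorts.
#' @param fdr permutation FDR in [0, 1].
#' @param floor FDR substitution for zeros.
#' @return numeric score vector.
#' @export
combined_score <- function(t1, t2, fdr, floor = 1e-5) {
  if (any(fdr < 0 | fdr > 1, na.rm = TRUE)) stop("fdr must lie in [0, 1]")
  lf <- log10(pmax(fdr, floor))
  ifelse(t1 > 0 & t2 > 0, -lf, ifelse(t1 < 0 & t2 < 0, lf, 0))
}

#' Cross-disease concordance by permutation of score products
#'
#' Multiplies each gene's combined scores from the two diseases and compares
#' the product with a pooled null obtained by randomly re-pairing the two
#' score vectors across genes: in every permutation one vector is shuffled,
#' all products recomputed, and the products pooled over genes and
#' permutations. The per-gene FDR is the pooled proportion of null products
#' more extreme than the observed one (absolute-value extremeness by
#' default, sign-directional behind \code{directional}, as in
#' \code{\link{t_product_fdr}}). Counting is done in chunks so the full
#' pooled null (n_perm x genes values) is never materialised.
#'
#' @param s1,s2 named combined-score vectors (genes shared by name; unnamed
#'   vectors of equal length are paired positionally).
#' @param n_perm number of permutations (default 1e6).
#' @param seed permutation seed.
#' @param directional use the sign-directional extremeness rule.
#' @param chunk permutations per counting block.
#' @return data.frame of class \code{nd_concordance}: gene, s1, s2, product,
#'   fdr.
#' @export
cross_disease_fdr <- function(s1, s2, n_perm = 1e6, seed = 1L,
                              directional = FALSE, chunk = 1000L) {
  if (!is.null(names(s1)) && !is.null(names(s2))) {
    shared <- intersect(names(s1), names(s2))
    if (length(shared) < 2) stop("no shared gene universe")
    s1 <- s1[shared]; s2 <- s2[shared]
  } else if (length(s1) != length(s2)) {
    stop("unnamed score vectors must have equal length")
  }
  g <- length(s1)
  obs <- s1 * s2
  pos <- obs >= 0
  # counts accumulated chunk-wise against sorted null values (findInterval
  # on a sorted vector gives #{null <= x}; left.open gives #{null < x})
  count <- numeric(g)
  with_seed(seed, {
    done <- 0
    while (done < n_perm) {
      b <- min(chunk, n_perm - done)
      nullv <- unlist(lapply(seq_len(b), function(i) s1 * sample(s2)),
                      use.names = FALSE)
      if (!directional) nullv <- abs(nullv)
      nullv <- sort(nullv)
      nn <- length(nullv)
      if (directional) {
        if (any(pos))
          count[pos] <- count[pos] +
            (nn - findInterval(obs[pos], nullv, left.open = TRUE))
        if (any(!pos))
          count[!pos] <- count[!pos] + findInterval(obs[!pos], nullv)
      } else {
        count <- count +
          (nn - findInterval(abs(obs), nullv, left.open = TRUE))
      }
      done <- done + b
    }
  })
  out <- data.frame(gene = if (!is.null(names(s1))) names(s1)
                           else seq_len(g),
                    s1 = s1, s2 = s2, product = obs,
                    fdr = count / (n_perm * g), row.names = NULL,
                    stringsAsFactors = FALSE)
  class(out) <- c("nd_concordance", "data.frame")
  out
}
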