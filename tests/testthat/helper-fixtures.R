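# Shared fixtures and independent oracles for the test suite.
# Fixtures are generated in code; oracles are deliberately naive
# implementations kept independent of the package's computation paths.

# Small simulation shared across files (memoised per session).
small_config <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- sim_config(n_genes = 400, n_cells_per_type = rep(60L, 4),
                           seed = 11L)
    cache
  }
})

small_reference <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_reference(small_config())
    cache
  }
})

# Reference after cell QC, with a signature (memoised).
small_signature_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ref <- small_reference()
      keep <- filter_cells(compute_cell_qc(ref))$kept
      refF <- ref
      refF$counts <- ref$counts[, keep]
      refF$cell_type <- ref$cell_type[keep]
      refF$true_type <- ref$true_type[keep]
      vd <- decompose_variance(refF, genes = filter_genes_sc(refF))
      sig <- build_signature(refF, genes = rownames(vd)[vd$retain])
      cache <<- list(ref = refF, vardecomp = vd, signature = sig)
    }
    cache
  }
})

# Brute-force non-negative least squares on K columns by enumerating active
# sets (constrained QP oracle; feasible subset with smallest SSE).
nnls_bruteforce <- function(S, y) {
  K <- ncol(S)
  best <- NULL
  for (mask in 0:(2^K - 1)) {
    active <- which(bitwAnd(mask, 2^(seq_len(K) - 1)) > 0)
    coef <- numeric(K)
    if (length(active) > 0) {
      b <- tryCatch(qr.solve(S[, active, drop = FALSE], y),
                    error = function(e) NULL)
      if (is.null(b) || any(b < -1e-12)) next
      coef[active] <- pmax(b, 0)
    }
    sse <- sum((y - S %*% coef)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(coef = coef, sse = sse)
  }
  best$coef
}

# Brute-force running-sum enrichment score at weight 0 (classical KS):
# walks the ranked list step by step.
es_bruteforce_w0 <- function(stat, set_genes) {
  ord <- order(-stat, names(stat))
  genes <- names(stat)[ord]
  hit <- genes %in% set_genes
  nh <- sum(hit); nm <- length(genes) - nh
  run <- 0; best <- 0
  for (i in seq_along(genes)) {
    run <- run + if (hit[i]) 1 / nh else -1 / nm
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Brute-force Spearman correlation with average ranks for ties.
spearman_bruteforce <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Cohort preparation used by model-level tests: deconvolve with the supplied
# signature, filter, normalize, encode covariates.
prep_cohort <- function(bulk, sig, profile) {
  est <- estimate_composition(bulk, sig)
  keep <- filter_low_neuron_samples(est)$kept
  counts <- bulk$counts[, keep, drop = FALSE]
  meta <- bulk$metadata[bulk$metadata$sample %in% keep, , drop = FALSE]
  norm <- normalize_bulk(structure(list(counts = counts,
                                        platform = bulk$platform),
                                   class = "nd_bulk"))
  if (bulk$platform == "rnaseq") {
    kg <- filter_genes_bulk(cpm(counts), L = min(colSums(counts)) / 1e6,
                            N = min(table(meta$disease)))
    norm <- norm[kg, , drop = FALSE]
  }
  cov <- encode_covariates(meta, est$fractions[keep, "neuron"], profile)
  list(norm = norm, cov = cov, meta = meta, est = est)
}

# Local RNG sandbox for test-side draws.
with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  force(expr)
}

# Dirichlet draws for constructing mixture proportion designs in tests.
rdirichlet_test <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  x / rowSums(x)
}
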