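test_that("CPM arithmetic, scale invariance and guards", {
  m <- matrix(c(5, 15), 2, 1)
  expect_equal(as.vector(cpm(m)), c(250000, 750000))
  m2 <- matrix(rpois(40, 30), 10, 4)
  doubled <- m2; doubled[, 2] <- 2 * m2[, 2]
  expect_equal(cpm(m2), cpm(doubled))
  single <- matrix(c(7, 0), 2, 1)
  expect_equal(cpm(single)[1, 1], 1e6)
  expect_error(cpm(matrix(0, 3, 2)), "zero library")
})

test_that("bulk gene filter implements CPM > 10/L in at least N samples", {
  # L = 20 million -> threshold 0.5 CPM
  cm <- rbind(at_thr = rep(0.5, 5),          # never strictly above
              above_n1 = c(0.6, 0.6, 0.4, 0.4, 0.4),  # above in N-1 = 2
              above_n = c(0.6, 0.6, 0.6, 0.4, 0.4),   # above in exactly N
              high = rep(10, 5))
  kept <- filter_genes_bulk(cm, L = 20, N = 3)
  expect_identical(kept, c("above_n", "high"))
  expect_error(filter_genes_bulk(cm, L = 0, N = 3), "positive")
  expect_error(filter_genes_bulk(cm, L = 20, N = 0), "at least 1")
  # result independent of sample order
  expect_identical(filter_genes_bulk(cm[, 5:1], L = 20, N = 3), kept)
})

test_that("quantile normalization matches the hand-computed 3x3 rank-mean table", {
  m <- matrix(c(2, 5, 8,
                4, 1, 9,
                6, 3, 1), 3, 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2", "s3")))
  # sorted columns: (2,5,8), (1,4,9), (1,3,6); rank means 4/3, 4, 23/3
  expected <- matrix(c(4 / 3, 4, 23 / 3,
                       4, 4 / 3, 23 / 3,
                       23 / 3, 4, 4 / 3), 3, 3, dimnames = dimnames(m))
  expect_equal(quantile_normalize(m), expected)
  # defining property: per-sample sorted vectors identical
  qn <- quantile_normalize(matrix(rnorm(60), 12, 5))
  sorted <- apply(qn, 2, sort)
  expect_lt(max(abs(sorted - sorted[, 1])), 1e-12)
  # idempotent
  expect_equal(quantile_normalize(qn), qn)
  # identical samples unchanged
  same <- matrix(c(1, 3, 7, 1, 3, 7), 3, 2)
  expect_equal(quantile_normalize(same), same)
  expect_error(quantile_normalize(matrix(1:3, 3, 1)), "2 samples")
})

test_that("covariate encoding dichotomizes, centers and forms the interaction", {
  md <- data.frame(sample = sprintf("s%d", 1:6),
                   disease = c(1, 1, 1, 1, 0, 0),
                   rin = c(8.5, 8.6, 9.2, 7.0, 8.5, 10),
                   age = c(70, 75, 80, 85, 90, 65),
                   sex = c(1, 0, 1, 0, 1, 0))
  neuronal <- c(0.8, 0.7, 0.6, 0.75, 0.85, 0.9)
  cv <- encode_covariates(md, neuronal, "ad_rnaseq")
  # RIN exactly at the cut is low
  expect_identical(cv$rin_high, c(0L, 1L, 1L, 0L, 0L, 1L))
  expect_lt(abs(mean(cv$disease_c)), 1e-12)
  expect_lt(abs(mean(cv$neuronal_c)), 1e-12)
  expect_equal(cv$interaction, cv$disease_c * cv$neuronal_c)
  expect_error(encode_covariates(md[, -3], neuronal, "ad_rnaseq"), "rin")
  # microarray profile: degradation slope dichotomized at 5
  md2 <- data.frame(disease = c(1, 0, 1, 0), age = c(70, 72, 74, 76),
                    degradation_slope = c(4.9, 5.0, 5.1, 7))
  cv2 <- encode_covariates(md2, rep(0.7, 4), "pd_microarray")
  expect_identical(cv2$degradation, c(0L, 0L, 1L, 1L))
})

test_that("PCA QC finds a planted composition axis and conserves variance", {
  set.seed(6)
  n <- 40
  fn <- runif(n, 0.4, 0.9)
  load <- rnorm(300, 0, 2)
  mat <- outer(load, fn) + matrix(rnorm(300 * n, 0, 0.3), 300, n)
  colnames(mat) <- sprintf("s%02d", 1:n)
  md <- data.frame(disease = rep(c(1, 0), n / 2), age = rnorm(n, 75, 5))
  qc <- pca_qc(mat, md, neuronal = fn)
  expect_gte(abs(qc$correlations["PC1", "neuronal"]), 0.9)
  expect_lt(abs(sum(qc$var_explained) - 100), 1e-8)
  # duplicated sample set: loadings pair up identically
  qc2 <- pca_qc(cbind(mat, mat))
  half <- seq_len(n)
  expect_lt(max(abs(qc2$scores[half, 1] - qc2$scores[half + n, 1])), 1e-6)
})

test_that("correlation clustering flags an independent noise sample and only it", {
  set.seed(7)
  base <- rnorm(200, 5, 2)
  mat <- sapply(1:15, function(i) base + rnorm(200, 0, 0.4))
  mat <- cbind(mat, noise = rnorm(200, 5, 2))
  colnames(mat) <- c(sprintf("s%02d", 1:15), "noise")
  res <- correlation_cluster_qc(mat)
  expect_identical(res$flagged, "noise")
  # identical samples: distance zero, merged first
  m2 <- cbind(a = base, b = base, c = base + rnorm(200, 0, 3),
              d = base + rnorm(200, 0, 3) + 5)
  res2 <- correlation_cluster_qc(m2)
  expect_equal(min(res2$first_merge_height[c("a", "b")]), 0)
  expect_identical(res2$hclust$merge[1, ], c(-1L, -2L))
  # homogeneous cohort: nothing flagged
  res3 <- correlation_cluster_qc(mat[, 1:15])
  expect_length(res3$flagged, 0)
})

test_that("marker checks find planted neuronal loss and handle degenerate genes", {
  # tight composition spread + low dispersion so the arm shift dominates the
  # within-arm variation (marginal marker tests are weak in wide cohorts)
  cfg <- sim_config(n_genes = 400, n_cells_per_type = rep(30L, 4),
                    composition_concentration = 100, dispersion = 0.005,
                    cohort_sizes = list(
                      ad = list(discovery = c(diseased = 60, control = 60),
                                validation = c(diseased = 5, control = 5)),
                      pd = list(discovery = c(diseased = 5, control = 5),
                                validation = c(diseased = 5, control = 5))),
                    seed = 23)
  ref <- simulate_reference(cfg)
  bulk <- simulate_bulk_cohort(cfg, ref, "ad", "discovery")
  norm <- normalize_bulk(bulk)
  neuron_m <- utils::head(
    cfg$genes[!is.na(cfg$marker_type) & cfg$marker_type == "neuron"], 8)
  res <- marker_checks(norm, bulk$metadata,
                       list(neuron = neuron_m, absent = "not_a_gene"))
  expect_identical(res$missing, "not_a_gene")
  nm <- res$table[res$table$type == "neuron", ]
  expect_true(all(nm$mean_diff < 0))       # down in the diseased arm
  expect_gt(mean(nm$fdr < 0.05), 0.7)
  # zero variance in both arms: NA, not an error
  norm2 <- unclass(norm)[1:3, ]
  norm2["g00001", ] <- 1
  res2 <- marker_checks(norm2, bulk$metadata, list(x = "g00001"))
  expect_true(is.na(res2$table$t[1]))
})

test_that("null marker tables stay near-uniform", {
  set.seed(10)
  mat <- matrix(rnorm(1000 * 30), 1000, 30,
                dimnames = list(sprintf("n%04d", 1:1000), NULL))
  md <- data.frame(disease = rep(c(1, 0), 15))
  res <- marker_checks(mat, md, list(all = rownames(mat)))
  expect_lt(mean(res$table$p < 0.05), 0.08)
  expect_lt(mean(res$table$fdr < 0.05), 0.01)
})
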