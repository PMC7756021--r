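test_that("simulators are pure functions of (config, seed)", {
  cfg <- sim_config(n_genes = 150, n_cells_per_type = rep(10L, 4), seed = 5)
  r1 <- simulate_reference(cfg, seed = 3)
  r2 <- simulate_reference(cfg, seed = 3)
  expect_identical(r1$counts, r2$counts)
  expect_identical(r1$cell_type, r2$cell_type)
  b1 <- simulate_bulk_cohort(cfg, r1, "ad", "validation", seed = 4)
  b2 <- simulate_bulk_cohort(cfg, r1, "ad", "validation", seed = 4)
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$metadata, b2$metadata)
  m1 <- simulate_mixtures(r1, diag(4), depth = 1000, seed = 6)
  m2 <- simulate_mixtures(r1, diag(4), depth = 1000, seed = 6)
  expect_identical(m1$counts, m2$counts)
  sc <- stats::setNames(rnorm(150), cfg$genes)
  p1 <- simulate_perturbagens(cfg, sc, seed = 7)
  p2 <- simulate_perturbagens(cfg, sc, seed = 7)
  expect_identical(p1$zscores, p2$zscores)
})

test_that("config validates and partitions genes into single effect classes", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(mrna_content = c(1, 1, 0, 1)), "positive")
  expect_error(sim_config(ad_fraction_means = list(
    control = c(0.5, 0.5, 0.5, 0.5), diseased = c(0.2, 0.1, 0.6, 0.1))),
    "sum to 1")
  cfg <- small_config()
  expect_length(cfg$effect_class, cfg$n_genes)
  expect_true(all(cfg$effect_class %in% c("systemic", "composition_driven",
                                          "interaction", "covariate_only",
                                          "null")))
  # systemic effects only on systemic genes; interaction only on interaction
  expect_true(all(cfg$beta_disease[cfg$effect_class != "systemic"] == 0))
  expect_true(all(cfg$beta_disease[cfg$effect_class == "systemic"] != 0))
  expect_true(all(cfg$beta_interaction[cfg$effect_class != "interaction"] == 0))
})

test_that("reference sample means converge to baseline in the noiseless limit", {
  cfg <- sim_config(n_genes = 120, n_cells_per_type = c(2000L, 2L, 2L, 2L),
                    dispersion = 1e-10, frac_degenerate = 0,
                    n_mislabeled = 0L, seed = 21)
  ref <- simulate_reference(cfg)
  astro <- ref$counts[, ref$true_type == "astrocyte"]
  emp <- rowMeans(astro)
  expected <- cfg$baseline[, "astrocyte"]
  # compare profiles up to the common library scaling
  ratio <- (emp / sum(emp)) / (expected / sum(expected))
  hi <- expected > quantile(expected, 0.25)  # low-rate genes are MC-noisy
  expect_lt(max(abs(ratio[hi] - 1)), 0.05)
})

test_that("planted mislabeled cells are exactly bookkept", {
  ref <- small_reference()
  expect_identical(sum(ref$cell_type != ref$true_type),
                   small_config()$n_mislabeled)
})

test_that("bulk truth records planted coefficients by construction", {
  cfg <- small_config()
  bulk <- simulate_bulk_cohort(cfg, small_reference(), "ad", "discovery")
  expect_true(all(bulk$truth$beta_disease[bulk$truth$class == "null"] == 0))
  expect_true(all(abs(bulk$truth$beta_disease[bulk$truth$class ==
                                                "systemic"]) == 1))
  expect_true(all(abs(rowSums(bulk$true_fractions) - 1) < 1e-12))
  expect_true(all(bulk$true_fractions >= 0))
  expect_identical(nrow(bulk$metadata), ncol(bulk$counts))
  expect_error(simulate_bulk_cohort(cfg, small_reference(), "huntington"),
               "arg")
})

test_that("a systemic +1 log2 gene doubles expected expression when composition is frozen", {
  cfg <- sim_config(n_genes = 300, n_cells_per_type = rep(20L, 4),
                    dispersion = 1e-10, composition_concentration = 1e7,
                    glia_concentration = 1e7,
                    covariate_effects = c(age = 0, sex = 0, rin = 0,
                                          batch = 0),
                    cohort_sizes = list(
                      ad = list(discovery = c(diseased = 150, control = 150),
                                validation = c(diseased = 5, control = 5)),
                      pd = list(discovery = c(diseased = 5, control = 5),
                                validation = c(diseased = 5, control = 5))),
                    seed = 31)
  ref <- simulate_reference(cfg)
  bulk <- simulate_bulk_cohort(cfg, ref, "ad", "discovery")
  cp <- cpm(bulk$counts)
  d <- bulk$metadata$disease == 1
  up <- cfg$genes[cfg$beta_disease == 1]
  ratio <- rowMeans(cp[up, d]) / rowMeans(cp[up, !d])
  expect_lt(max(abs(ratio - 2)), 0.15)
  null_g <- cfg$genes[cfg$effect_class == "null"]
  ratio0 <- rowMeans(cp[null_g, d]) / rowMeans(cp[null_g, !d])
  expect_lt(max(abs(ratio0 - 1)), 0.1)
})

test_that("AD-like arms draw neuronal fractions from the configured shifted distributions", {
  cfg <- sim_config(n_genes = 60, n_cells_per_type = rep(5L, 4),
                    cohort_sizes = list(
                      ad = list(discovery = c(diseased = 5000,
                                              control = 5000),
                                validation = c(diseased = 5, control = 5)),
                      pd = list(discovery = c(diseased = 2000,
                                              control = 2000),
                                validation = c(diseased = 5, control = 5))),
                    seed = 41)
  ref <- simulate_reference(cfg)
  bulk <- simulate_bulk_cohort(cfg, ref, "ad", "discovery")
  d <- bulk$metadata$disease == 1
  # Beta(conc*m, conc*(1-m)) means 0.60 / 0.70; MC error ~ sd/sqrt(n)
  mc <- 4 * sqrt(0.7 * 0.3 / 11) / sqrt(5000)
  expect_lt(abs(mean(bulk$true_fractions[d, "neuron"]) - 0.60), mc)
  expect_lt(abs(mean(bulk$true_fractions[!d, "neuron"]) - 0.70), mc)
  pd <- simulate_bulk_cohort(cfg, ref, "pd", "discovery")
  dp <- pd$metadata$disease == 1
  expect_lt(abs(mean(pd$true_fractions[dp, "neuron"]) -
                  mean(pd$true_fractions[!dp, "neuron"])), 0.02)
})

test_that("mixtures conserve depth and match pooled pool profiles", {
  ref <- small_reference()
  prop <- rbind(c(0, 0, 1, 0), c(0.25, 0.25, 0.25, 0.25))
  mix <- simulate_mixtures(ref, prop, depth = 1e6, seed = 9)
  expect_true(all(colSums(mix$counts) == 1e6))
  # single-source mixture: chi-square goodness of fit to the neuron pool
  pool <- rowSums(ref$counts[, ref$cell_type == "neuron"])
  p <- pool / sum(pool)
  keep <- p > 5e-5  # expected count >= 50
  gof <- suppressWarnings(
    chisq.test(mix$counts[keep, 1], p = p[keep], rescale.p = TRUE))
  expect_gt(gof$p.value, 0.01)
  expect_error(simulate_mixtures(ref, rbind(c(0.5, 0.5, 0.5, 0.5)), 100),
               "sum to 1")
})

test_that("scaled-depth mixtures preserve expected per-type gene shares", {
  ref <- small_reference()
  set.seed(33)
  prop <- rdirichlet_test(300, c(0.8, 0.2, 2.2, 0.8))
  colnames(prop) <- ref$cell_types
  mix <- simulate_mixtures(ref, prop, depth = 3.5e5, seed = 13)
  pools <- sapply(ref$cell_types, function(t)
    rowSums(ref$counts[, ref$cell_type == t]))
  pool_p <- sweep(pools, 2, colSums(pools), "/")
  # analytic expectation of total counts over all mixtures
  expected <- 3.5e5 * (pool_p %*% colSums(prop))
  emp <- rowSums(mix$counts)
  hi <- expected > 2e4
  expect_lt(max(abs(emp[hi] / expected[hi] - 1)), 0.02)
})

test_that("perturbagen panel plants recoverable compound roles", {
  cfg <- small_config()
  sc <- stats::setNames(rnorm(cfg$n_genes), cfg$genes)
  panel <- simulate_perturbagens(cfg, sc, seed = 17)
  # zero-noise reverser: exact anti-rank
  rev1 <- names(panel$planted_roles)[panel$planted_roles == "reverser"][1]
  j <- which(panel$conditions$compound == rev1)[1]
  expect_equal(cor(panel$zscores[, j], sc, method = "spearman"), -1)
  # each compound replicated across the configured cell lines
  cond1 <- panel$conditions[panel$conditions$compound == rev1, ]
  expect_equal(length(unique(cond1$cell_line)),
                   cfg$perturbagen$n_cell_lines)
  expect_equal(length(unique(panel$conditions$compound)),
                   cfg$perturbagen$n_compounds)
  # every condition maps to exactly one compound
  expect_true(!any(duplicated(panel$conditions$condition)))
  expect_error(simulate_perturbagens(cfg, sc[1:50]), "at least 100")
})

test_that("neutral compounds are null at large gene universes", {
  cfg <- sim_config(n_genes = 10000, n_cells_per_type = rep(2L, 4),
                    perturbagen = list(n_compounds = 25, n_cell_lines = 1,
                                       n_doses = 1, n_reversers = 1,
                                       n_mimickers = 1, n_confounders = 1,
                                       signal = 2, noise_sd = 0.3),
                    seed = 19)
  sc <- with_seed_test(3, stats::setNames(rnorm(1e4), cfg$genes))
  panel <- simulate_perturbagens(cfg, sc, seed = 23)
  neutral <- names(panel$planted_roles)[panel$planted_roles == "neutral"]
  j <- which(panel$conditions$compound %in% neutral)
  rho <- as.vector(cor(panel$zscores[, j], sc, method = "spearman"))
  # null rank correlation at n = 1e4 has sd ~ 0.01
  expect_gt(mean(abs(rho) < 0.05), 0.99)
})
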