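# helper to assemble a minimal nd_fits object directly
make_fits <- function(beta, u, sigma2, df, coef_name = "disease_c") {
  g <- sprintf("g%02d", seq_along(beta))
  structure(list(
    coefficients = matrix(beta, length(beta), 1,
                          dimnames = list(g, coef_name)),
    stdev_unscaled = stats::setNames(u, coef_name),
    sigma2 = stats::setNames(sigma2, g), df = df,
    t_ordinary = matrix(beta / (sqrt(sigma2) * u), length(beta), 1,
                        dimnames = list(g, coef_name)),
    design = NULL), class = "nd_fits")
}

test_that("per-gene OLS matches the normal-equations oracle and interpolates noiseless data", {
  set.seed(2)
  n <- 12
  cov <- data.frame(disease_c = scale(rep(c(1, 0), each = 6), scale = FALSE),
                    age = rnorm(n, 75, 5))
  X <- cbind(1, as.matrix(cov))
  B <- matrix(c(2, 1.5, -0.02, 0.5, 0, 0.01), 2, 3, byrow = TRUE)
  Y <- B %*% t(X)  # noiseless: exact interpolation
  rownames(Y) <- c("gA", "gB")
  fits <- fit_models(Y, cov)
  expect_lt(max(abs(fits$coefficients - B[, c(1, 2, 3)])), 1e-10)

  # noisy data against explicit normal equations and lm()
  Yn <- Y + matrix(rnorm(2 * n, 0, 0.3), 2, n)
  fits2 <- fit_models(Yn, cov)
  beta_oracle <- solve(t(X) %*% X) %*% t(X) %*% t(Yn)
  expect_lt(max(abs(t(fits2$coefficients) - beta_oracle)), 1e-12)
  lmfit <- lm(Yn[1, ] ~ cov$disease_c + cov$age)
  expect_equal(unname(fits2$coefficients[1, ]), unname(coef(lmfit)),
               tolerance = 1e-12)
  se_lm <- summary(lmfit)$coefficients[, "Std. Error"]
  expect_equal(unname(sqrt(fits2$sigma2[1]) * fits2$stdev_unscaled),
               unname(se_lm), tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear term", {
  cov <- data.frame(disease_c = c(-0.5, -0.5, 0.5, 0.5, -0.5, 0.5),
                    copy = c(-0.5, -0.5, 0.5, 0.5, -0.5, 0.5))
  Y <- matrix(rnorm(12), 2, 6)
  expect_error(fit_models(Y, cov), "rank deficient.*copy")
  expect_error(fit_models(Y, data.frame(interaction = 1:6)), "requires both")
})

test_that("moderation reproduces the hand-computed posterior table and limits", {
  beta <- c(1, -0.5, 0.2, 2, -1)
  s2 <- c(0.1, 0.2, 0.5, 1, 2)
  fits <- make_fits(beta, u = 0.25, sigma2 = s2, df = 10)
  eff <- moderate(fits, d0 = 4, s0_2 = 0.5)
  expect_equal(unname(eff$s2_post),
               c(0.214285714285714, 0.285714285714286, 0.5,
                 0.857142857142857, 1.571428571428571), tolerance = 1e-10)
  expect_equal(unname(eff$t[, 1]),
               c(8.640987597877148, -3.741657386773941, 1.131370849898476,
                 8.640987597877148, -3.190896140869863), tolerance = 1e-10)
  # d0 -> 0: moderated t equals the ordinary t
  eff0 <- moderate(fits, d0 = 0, s0_2 = 0.5)
  expect_equal(eff0$t, fits$t_ordinary, tolerance = 1e-12)
  # d0 = Inf: every posterior variance equals s0^2
  effI <- moderate(fits, d0 = Inf, s0_2 = 0.5)
  expect_true(all(effI$s2_post == 0.5))
})

test_that("prior estimation matches limma's squeezeVar on both branches", {
  set.seed(3)
  df <- 14
  s2 <- rchisq(300, df) / df * exp(rnorm(300, 0, 0.8))
  fits <- make_fits(rnorm(300), u = 0.2, sigma2 = s2, df = df)
  eff <- moderate(fits)
  sq <- limma::squeezeVar(s2, df)
  expect_equal(eff$d0, sq$df.prior, tolerance = 1e-10)
  expect_equal(unname(eff$s2_post), unname(sq$var.post), tolerance = 1e-10)
  # homogeneous variances: full-shrinkage branch, handled without overflow
  s2h <- rep(1.3, 300)
  effh <- moderate(make_fits(rnorm(300), 0.2, s2h, df))
  expect_true(is.infinite(effh$d0))
  expect_true(all(is.finite(effh$t)))
  expect_true(all(effh$s2_post == effh$s0_2))
})

test_that("moderated t equals limma's on a full pipeline fit", {
  set.seed(4)
  n <- 24; G <- 150
  cov <- data.frame(disease_c = scale(rep(c(1, 0), each = 12),
                                      scale = FALSE)[, 1],
                    age = rnorm(n, 70, 6))
  Y <- matrix(rnorm(G * n), G, n, dimnames = list(sprintf("g%03d", 1:G),
                                                  NULL))
  eff <- moderate(fit_models(Y, cov))
  X <- cbind(1, as.matrix(cov))
  eb <- limma::eBayes(limma::lmFit(Y, X))
  expect_equal(unname(eff$t[, "disease_c"]), unname(eb$t[, "disease_c"]),
               tolerance = 1e-8)
  expect_equal(unname(eff$p[, "disease_c"]),
               unname(eb$p.value[, "disease_c"]), tolerance = 1e-8)
})

test_that("B statistic is finite and monotone in |t| at fixed variance", {
  fits <- make_fits(seq(-3, 3, length.out = 20), u = 0.3,
                    sigma2 = rep(1, 20), df = 10)
  eff <- moderate(fits, d0 = 5, s0_2 = 1)
  expect_true(all(is.finite(eff$B)))
  o <- order(abs(eff$t[, 1]))
  expect_true(all(diff(eff$B[o, 1]) >= -1e-12))
})

test_that("BH adjustment and DE calling follow step-up semantics and strict cuts", {
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  fits <- make_fits(c(3, 2.9, 0.1, -0.05, 0.02, 3.2, -2.8, 0.01, 0, 0.03),
                    u = 0.3, sigma2 = rep(0.8, 10), df = 12)
  eff <- moderate(fits, d0 = 4, s0_2 = 0.8)
  # force a known FDR landscape
  eff$fdr[, 1] <- c(0.049, 0.05, 0.2, 0.5, 0.9, 0.001, 0.04, 0.8, 1, 0.109)
  called <- call_de(eff, fdr_cut = 0.05)$disease_c
  expect_true("g01" %in% called$gene)    # 0.049 called
  expect_false("g02" %in% called$gene)   # 0.05 exactly: not called
  expect_identical(called$direction[called$gene == "g07"], "down")
  called11 <- call_de(eff, fdr_cut = 0.11)$disease_c
  expect_true("g10" %in% called11$gene)  # microarray profile cut
})

test_that("centering shrinks the disease-interaction design correlation on unbalanced cohorts", {
  set.seed(9)
  disease <- c(rep(1, 40), rep(0, 12))
  neuronal <- c(rnorm(40, 0.6, 0.1), rnorm(12, 0.7, 0.1))
  dc <- disease - mean(disease); nc <- neuronal - mean(neuronal)
  with_centering <- abs(cor(dc, dc * nc))
  without <- abs(cor(disease, disease * neuronal))
  expect_lt(with_centering, without)
})

test_that("null cohorts stay at the nominal false-call rate", {
  cfg <- sim_config(n_genes = 600, n_cells_per_type = rep(20L, 4),
                    class_fractions = c(composition_driven = 0,
                                        systemic = 0, interaction = 0,
                                        covariate_only = 0),
                    covariate_effects = c(age = 0, sex = 0, rin = 0,
                                          batch = 0),
                    seed = 29)
  ref <- simulate_reference(cfg)
  bulk <- simulate_bulk_cohort(cfg, ref, "ad", "discovery")
  norm <- normalize_bulk(bulk)
  cov <- encode_covariates(bulk$metadata, bulk$true_shares[, "neuron"],
                           "ad_rnaseq")
  eff <- moderate(fit_models(norm, cov))
  expect_lt(mean(eff$fdr[, "disease_c"] < 0.05), 0.07)
})
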