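test_that("IBS kinship equals the brute-force pairwise loop", {
  set.seed(10)
  gm <- random_gm(50, 10, missing = 0.15)
  K <- ibs_kinship(gm)$K
  for (i in 1:10) for (j in 1:10) {
    a <- gm$calls[, i]; b <- gm$calls[, j]
    both <- !is.na(a) & !is.na(b)
    expect_equal(K[i, j], mean(a[both] == b[both]))
  }
  expect_true(all(diag(K) == 1))
  # identical strains / complementary strains
  v <- data.frame(snp_id = c("a", "b"), chrom = "c", pos = 1:2,
                  ref = "A", alt = "G")
  gm2 <- genotype_matrix(v, c("x", "y", "z"),
                         matrix(c(0L, 1L, 0L, 1L, 1L, 0L), 2))
  K2 <- ibs_kinship(gm2)$K
  expect_equal(K2["x", "y"], 1)
  expect_equal(K2["x", "z"], 0)
})

test_that("mixed model reduces to OLS when K = I", {
  set.seed(11)
  n <- 40
  y <- rnorm(n); x <- rbinom(n, 1, 0.5)
  fit <- fit_mixed_model(y, cbind(1, x), diag(n))
  expect_equal(fit$loglik, as.numeric(logLik(lm(y ~ x))),
               tolerance = 1e-6)
})

test_that("profile loglik equals direct multivariate-normal density", {
  set.seed(12)
  for (i in 1:8) {
    n <- sample(8:20, 1)
    G <- matrix(rbinom(n * 60, 1, 0.5), n)
    K <- (tcrossprod(G) + tcrossprod(1 - G)) / 60
    x <- rnorm(n)
    y <- rnorm(n) + x
    X <- cbind(1, x)
    fit <- fit_mixed_model(y, X, K)
    expect_equal(fit$loglik,
                 mvn_loglik(y, X, fit$beta, fit$sigma_g2, fit$sigma_e2,
                            K),
                 tolerance = 1e-5)
  }
})

test_that("variance-component ratio is recovered on structured kinship", {
  # scaled-down recovery check; the full 200-seed version runs in the
  # acceptance suite
  ratios <- vapply(1:30, function(s) {
    cfg <- panel_sim_config(n_groups = 10, strains_per_group = 20,
                            n_snps = 200, missing_rate_range = c(0, 0),
                            seed = s)
    K <- ibs_kinship(simulate_strain_panel(cfg))$K
    n <- nrow(K)
    withr::with_seed(s + 5000, {
      ev <- eigen(K, symmetric = TRUE)
      ev$values[ev$values < 0] <- 0
      y <- 1 + drop(ev$vectors %*% (sqrt(2 * ev$values) * rnorm(n))) +
        rnorm(n)
    })
    fit <- fit_mixed_model(y, K = K)
    fit$sigma_g2 / fit$sigma_e2
  }, 0)
  expect_lt(abs(median(ratios) - 2) / 2, 0.35)
})

test_that("LRT scan matches ordinary-regression LRT when K = I", {
  set.seed(13)
  gm <- random_gm(40, 25, missing = 0)
  y <- rnorm(25)
  res <- lrt_scan(gm, y, diag(25))
  for (i in seq_len(nrow(gm$calls))) {
    x <- gm$calls[i, ]
    if (length(unique(x)) < 2) next
    l1 <- as.numeric(logLik(lm(y ~ x)))
    l0 <- as.numeric(logLik(lm(y ~ 1)))
    p_ols <- pchisq(2 * (l1 - l0), 1, lower.tail = FALSE)
    expect_lt(abs(-log10(res$p_value[i]) - -log10(p_ols)), 1e-4)
  }
})

test_that("LRT statistics are non-negative and order-invariant", {
  set.seed(14)
  gm <- random_gm(60, 20, missing = 0.1)
  y <- rnorm(20)
  K <- ibs_kinship(gm)$K
  res <- lrt_scan(gm, y, K)
  expect_true(all(res$lrt_stat >= 0))

  # permuting strain order leaves the scan unchanged
  perm <- sample(20)
  gmp <- genotype_matrix(gm$variants, gm$strains[perm],
                         gm$calls[, perm])
  resp <- lrt_scan(gmp, setNames(y, gm$strains)[perm], K[perm, perm])
  expect_equal(resp$p_value, res$p_value, tolerance = 1e-8)

  # affine phenotype rescaling leaves p-values unchanged
  resa <- lrt_scan(gm, 3 * y + 7, K)
  expect_equal(resa$p_value, res$p_value, tolerance = 1e-6)

  # monomorphic SNPs are flagged with p = 1
  gm$calls[1, ] <- 1L
  resm <- lrt_scan(gm, y, K)
  expect_true(resm$monomorphic[1])
  expect_equal(resm$p_value[1], 1)
})

test_that("null type-I error is calibrated (scaled-down)", {
  cfg <- panel_sim_config(n_groups = 5, strains_per_group = 10,
                          n_snps = 400, missing_rate_range = c(0, 0),
                          seed = 15)
  gm <- simulate_strain_panel(cfg)
  keep <- apply(gm$calls, 1, function(x) length(unique(x)) > 1)
  gm <- genotype_matrix(gm$variants[keep, ], gm$strains,
                        gm$calls[keep, ])
  K <- ibs_kinship(gm)$K
  y <- withr::with_seed(16, sample(rep(c(0, 1), each = 25)))
  res <- lrt_scan(gm, y, K)
  rate <- mean(res$p_value[!res$monomorphic] < 0.05)
  expect_gt(rate, 0.02)
  expect_lt(rate, 0.09)
})

test_that("the causal enhancer SNP is found in a synthetic panel", {
  hits <- 0; n_seeds <- 10
  for (s in seq_len(n_seeds)) {
    cfg <- panel_sim_config(n_groups = 10, strains_per_group = 5,
                            n_snps = 150,
                            missing_rate_range = c(0, 0), seed = s)
    gm <- simulate_strain_panel(cfg)
    model <- two_locus_trait_model(1e6, 35e6, penetrance = 1)
    plan <- data.frame(group = paste0("G", 1:10),
                       primary = "r",
                       enhancer = rep(c("E", "e"), 5))
    ann <- assign_trait_alleles(gm, model, plan)
    labels <- attr(ann, "trait_alleles")
    y <- setNames(as.numeric(labels$enhancer == "E"), labels$strain)
    res <- lrt_scan(ann, y, ibs_kinship(ann)$K)
    best <- res$snp_id[which.min(res$p_value)]
    if (best == "trait_enhancer") hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.8)
})

test_that("Bonferroni thresholds follow the test count", {
  thr <- significance_thresholds(13257)
  expect_equal(thr$stringent, 0.05 / 13257)
  expect_equal(signif(thr$stringent, 3), 3.77e-6)
  expect_equal(thr$moderate, 0.05)
  expect_equal(significance_thresholds(1)$stringent, 0.05)
  expect_error(significance_thresholds(0))
})
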