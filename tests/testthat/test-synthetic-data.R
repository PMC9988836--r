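test_that("panel simulation is deterministic and honors its config", {
  cfg <- panel_sim_config(n_groups = 3, strains_per_group = 4,
                          n_snps = 400, missing_rate_range = c(0.1, 0.1),
                          seed = 11)
  gm1 <- simulate_strain_panel(cfg)
  gm2 <- simulate_strain_panel(cfg)
  expect_identical(gm1$calls, gm2$calls)
  expect_identical(dim(gm1), c(400L, 12L))

  # missing fraction within 3 binomial SDs of the configured 0.1
  n <- length(gm1$calls)
  expect_lt(abs(mean(is.na(gm1$calls)) - 0.1),
            3 * sqrt(0.1 * 0.9 / n))

  # zero divergence at both levels -> all strains identical -> the
  # generator refuses (no polymorphic sites)
  cfg0 <- panel_sim_config(n_groups = 2, strains_per_group = 3,
                           n_snps = 50, between_group_divergence = 0,
                           within_group_diversity = 0,
                           missing_rate_range = c(0, 0), seed = 1)
  expect_error(simulate_strain_panel(cfg0), "polymorphic")

  # strains within a group are more similar than across groups
  cfgs <- panel_sim_config(n_groups = 2, strains_per_group = 5,
                           n_snps = 500, within_group_diversity = 0.01,
                           missing_rate_range = c(0, 0), seed = 2)
  gms <- simulate_strain_panel(cfgs)
  K <- ibs_kinship(gms)$K
  grp <- attr(gms, "groups")
  same <- outer(grp, grp, "==") & upper.tri(K)
  diff_ <- !outer(grp, grp, "==") & upper.tri(K)
  expect_gt(mean(K[same]), mean(K[diff_]))
})

test_that("the complementation rule gives the stated expectations", {
  pen <- 0.85
  expect_equal(susceptibility_prob("s", "e", pen), pen)
  expect_equal(susceptibility_prob("r", "e", pen), 0)
  expect_equal(susceptibility_prob("r", "E", pen), pen)
  expect_equal(susceptibility_prob("ko", "E", pen), 0)  # needs HRH1
  expect_equal(susceptibility_prob(c("ko", "r"), c("e", "E"), pen), pen)
  expect_equal(susceptibility_prob(c("ko", "s"), c("e", "e"), pen), pen)
})

test_that("trait alleles embed as rediscoverable genotype columns", {
  cfg <- panel_sim_config(n_groups = 2, strains_per_group = 3,
                          n_snps = 50, missing_rate_range = c(0, 0),
                          seed = 3)
  gm <- simulate_strain_panel(cfg)
  model <- two_locus_trait_model(1e6, 2e6, penetrance = 0.9)
  ann <- assign_trait_alleles(gm, model, data.frame(
    group = c("G1", "G2"), primary = c("r", "r"),
    enhancer = c("e", "E")))
  expect_true(all(c("trait_primary", "trait_enhancer") %in%
                    ann$variants$snp_id))
  enh <- ann$calls["trait_enhancer", ]
  grp <- attr(ann, "groups")
  expect_true(all(enh[grp == "G2"] == 1L))
  expect_true(all(enh[grp == "G1"] == 0L))
})

test_that("dose-response simulation matches its binomial expectations", {
  cfg <- panel_sim_config(n_groups = 2, strains_per_group = 1,
                          n_snps = 50, missing_rate_range = c(0, 0),
                          seed = 4)
  gm <- simulate_strain_panel(cfg)
  model <- two_locus_trait_model(1e6, 2e6, penetrance = 0.9)
  ann <- assign_trait_alleles(gm, model, data.frame(
    group = c("G1", "G2"), primary = c("s", "r"),
    enhancer = c("e", "e")))
  dr <- simulate_dose_response(ann, doses = c(100, 50), 500, seed = 9)
  expect_identical(dr, simulate_dose_response(ann, c(100, 50), 500,
                                              seed = 9))
  res <- pool_doses(dr, ann$strains[attr(ann, "groups") == "G2"][1])
  expect_identical(res$affected, 0L)  # resistant, zero background
  sus <- pool_doses(dr, ann$strains[attr(ann, "groups") == "G1"][1])
  expect_lt(abs(sus$affected / sus$tested - 0.9),
            3 * sqrt(0.9 * 0.1 / sus$tested))
})

test_that("backcross recombination follows the Haldane map function", {
  # cm_per_mb = 0 -> no recombination anywhere
  model <- two_locus_trait_model(1e6, 25e6, penetrance = 0.9)
  bc0 <- simulate_backcross(
    backcross_sim_config(200, marker_pos = c(1e6, 20e6, 50e6),
                         cm_per_mb = 0, seed = 5), model)
  expect_true(all(bc0$genotypes[, 1] == bc0$genotypes[, 2] &
                    bc0$genotypes[, 2] == bc0$genotypes[, 3]))

  # two markers 50 Mb apart at 0.5 cM/Mb: Haldane r for 25 cM = 0.1967
  r_expected <- (1 - exp(-2 * 0.25)) / 2
  expect_equal(haldane_r(50e6, 0.5), r_expected)
  bc <- simulate_backcross(
    backcross_sim_config(2000, marker_pos = c(1e6, 51e6),
                         cm_per_mb = 0.5, seed = 6), model)
  rec <- mean(bc$genotypes[, 1] != bc$genotypes[, 2])
  expect_lt(abs(rec - r_expected),
            3 * sqrt(r_expected * (1 - r_expected) / 2000))

  # determinism
  cfg <- backcross_sim_config(50, marker_pos = c(1e6, 30e6),
                              cm_per_mb = 0.5, seed = 7)
  expect_identical(simulate_backcross(cfg, model)$genotypes,
                   simulate_backcross(cfg, model)$genotypes)
})

test_that("network simulation plants modules with Beta-distributed weights", {
  cfg <- network_sim_config(n_genes = 60, module_sizes = c(15),
                            within_weight_mean = 0.7,
                            between_weight_mean = 0.1,
                            weight_concentration = 30, seed = 8)
  net1 <- simulate_network(cfg)
  net2 <- simulate_network(cfg)
  expect_identical(net1$weights, net2$weights)
  expect_true(isSymmetric(net1$weights))
  expect_true(all(diag(net1$weights) == 0))
  mod <- attr(net1, "modules")$module1
  inside <- net1$weights[mod, mod]
  outside <- net1$weights[setdiff(net1$gene_ids, mod),
                          setdiff(net1$gene_ids, mod)]
  expect_lt(abs(mean(inside[upper.tri(inside)]) - 0.7), 0.05)
  expect_lt(abs(mean(outside[upper.tri(outside)]) - 0.1), 0.05)

  # degenerate Beta: infinite concentration gives constant weights
  cfg_inf <- network_sim_config(n_genes = 20, module_sizes = c(5),
                                within_weight_mean = 0.6,
                                between_weight_mean = 0.2,
                                weight_concentration = Inf, seed = 9)
  neti <- simulate_network(cfg_inf)
  modi <- attr(neti, "modules")$module1
  wi <- neti$weights[modi, modi]
  expect_true(all(wi[upper.tri(wi)] == 0.6))
})
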