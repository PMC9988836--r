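test_that("SNPs are assigned to the nearest gene within 1 Mb", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "chr6",
                      start = c(1000L, 5000000L),
                      end = c(2000L, 5100000L))
  assoc <- data.frame(
    snp_id = c("in_A", "edge_in", "edge_out", "far"),
    chrom = "chr6",
    pos = c(1500L, 2000L + 999999L, 2000L + 1000001L, 9000000L),
    p_value = rep(0.01, 4))
  res <- assign_snps_to_genes(assoc, genes, window = 1e6)
  asn <- setNames(res$assignments$gene_id, res$assignments$snp_id)
  expect_identical(unname(asn["in_A"]), "A")
  expect_equal(
    res$assignments$distance[res$assignments$snp_id == "in_A"], 0)
  # 999,999 bp away is assigned, 1,000,001 bp is not
  expect_identical(unname(asn["edge_in"]), "A")
  expect_true("edge_out" %in% res$unassigned)
  expect_true("far" %in% res$unassigned)

  # an exactly equidistant SNP goes to the lower-start gene:
  # gene A occupies bases 1..1000, gene B bases 2000..3000, so position
  # 1500 is 500 bp from each edge
  tie_genes <- data.frame(gene_id = c("B2", "A2"), chrom = "chr6",
                          start = c(1999L, 0L), end = c(3000L, 1000L))
  tie_assoc <- data.frame(snp_id = "tie", chrom = "chr6", pos = 1500L,
                          p_value = 0.01)
  tie_res <- assign_snps_to_genes(tie_assoc, tie_genes, window = 1e6)
  expect_identical(tie_res$assignments$gene_id, "A2")
})

test_that("assignment equals the brute-force all-pairs scan", {
  set.seed(50)
  for (rep in 1:5) {
    genes <- data.frame(gene_id = paste0("g", 1:8), chrom = "chr6",
                        start = sort(sample.int(1e7, 8)))
    genes$end <- genes$start + sample(1000:50000, 8)
    assoc <- data.frame(snp_id = paste0("s", 1:40), chrom = "chr6",
                        pos = sample.int(1.1e7, 40),
                        p_value = runif(40))
    res <- assign_snps_to_genes(assoc, genes, window = 1e6)
    for (i in seq_len(nrow(assoc))) {
      d <- pmax(0, genes$start + 1 - assoc$pos[i],
                assoc$pos[i] - genes$end)
      if (min(d) > 1e6) {
        expect_true(assoc$snp_id[i] %in% res$unassigned)
      } else {
        best <- genes$gene_id[order(d, genes$start)[1]]
        got <- res$assignments$gene_id[
          res$assignments$snp_id == assoc$snp_id[i]]
        expect_identical(got, best)
      }
    }
  }
})

test_that("gene association score is the max -log10 p over its SNPs", {
  genes <- data.frame(gene_id = c("A", "B"), chrom = "chr6",
                      start = c(0L, 10000L), end = c(1000L, 11000L))
  assoc <- data.frame(snp_id = c("s1", "s2", "s3"), chrom = "chr6",
                      pos = c(500L, 600L, 10500L),
                      p_value = c(1e-3, 1e-6, 1e-2))
  asn <- assign_snps_to_genes(assoc, genes)
  sc <- gene_assoc_score(assoc, asn, c("A", "B", "C"))
  expect_equal(unname(sc["A"]), 6)
  expect_equal(unname(sc["B"]), 2)
  expect_equal(unname(sc["C"]), 0)  # no SNP assigned
})

test_that("the combined score follows the two-component normalization", {
  # hand-evaluated two-gene example
  tab <- combined_score(c(A = 2, B = 1), c(A = 1, B = 3))
  expect_equal(tab$s_cg[tab$gene_id == "A"], 1 + 1 / 3)
  expect_equal(tab$s_cg[tab$gene_id == "B"], 0.5 + 1)
  expect_identical(tab$gene_id[1], "B")
  expect_identical(tab$rank, 1:2)

  # gene attaining both maxima scores exactly 2; bounds hold
  tab2 <- combined_score(c(A = 5, B = 2, C = 0),
                         c(A = 4, B = 1, C = 0))
  expect_equal(tab2$s_cg[tab2$gene_id == "A"], 2)
  expect_true(all(tab2$s_cg >= 0 & tab2$s_cg <= 2))

  # invariance under positive rescaling of either component
  tab3 <- combined_score(c(A = 20, B = 10), c(A = 1, B = 3))
  expect_equal(tab3$s_cg, tab$s_cg)
  tab4 <- combined_score(c(A = 2, B = 1), c(A = 0.25, B = 0.75))
  expect_equal(tab4$s_cg, tab$s_cg)

  # adding a gene that attains neither maximum leaves others unchanged
  tab5 <- combined_score(c(A = 2, B = 1, D = 0.5),
                         c(A = 1, B = 3, D = 0.1))
  expect_equal(tab5$s_cg[match(c("A", "B"), tab5$gene_id)],
               tab$s_cg[match(c("A", "B"), tab$gene_id)])

  # all-zero component warns and contributes nothing
  expect_warning(tab6 <- combined_score(c(A = 1, B = 2),
                                        c(A = 0, B = 0)),
                 "all-zero")
  expect_equal(tab6$s_cg[tab6$gene_id == "B"], 1)
})

test_that("the enhancer gene ranks first end-to-end on synthetic data", {
  # the causal gene is both the top association and inside a planted
  # functional module; s_cg must rank it first in most seeds
  hits <- 0; n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    net <- simulate_network(network_sim_config(
      n_genes = 100, module_sizes = c(15), within_weight_mean = 0.8,
      between_weight_mean = 0.1, seed = s))
    mod <- cluster_gene_set(attr(net, "modules")$module1, net)[[1]]
    ens <- train_ensemble(mod, net,
                          costs = 10^seq(-2, 2, length.out = 8),
                          seed = s + 100, n_svms = 25)
    cand <- net$gene_ids[1:40]          # module1 genes are 1:15
    func <- score_candidates(list(ens), cand)
    f_score <- setNames(func$neglog10_fpr, func$gene_id)

    # association component: the causal gene carries the best SNP
    causal <- cand[1]
    a_score <- setNames(rep(0, length(cand)), cand)
    withr::with_seed(s + 200, {
      a_score[] <- runif(length(cand), 0, 2)
      a_score[causal] <- 6
    })
    tab <- combined_score(a_score, f_score)
    if (tab$gene_id[1] == causal) hits <- hits + 1
  }
  expect_gte(hits / n_seeds, 0.9)
})
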