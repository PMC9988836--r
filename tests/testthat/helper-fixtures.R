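# Shared fixtures and independent oracles used across test files.

# small genotype matrix built in code
tiny_gm <- function() {
  variants <- data.frame(
    snp_id = c("s1", "s2", "s3"), chrom = "chr6",
    pos = c(100L, 200L, 300L), ref = c("A", "C", "G"),
    alt = c("G", "T", "A"), stringsAsFactors = FALSE)
  calls <- matrix(c(0L, 1L, NA, 1L, 0L, 1L), nrow = 3,
                  dimnames = list(variants$snp_id, c("strA", "BPL/1 J")))
  genotype_matrix(variants, c("strA", "BPL/1 J"), calls)
}

random_gm <- function(n_snps, n_strains, missing = 0.1) {
  variants <- data.frame(
    snp_id = sprintf("s%04d", seq_len(n_snps)), chrom = "chr6",
    pos = sort(sample.int(1e6, n_snps)), ref = "A", alt = "G",
    stringsAsFactors = FALSE)
  calls <- matrix(sample(c(0L, 1L), n_snps * n_strains, TRUE), n_snps)
  calls[runif(length(calls)) < missing] <- NA_integer_
  genotype_matrix(variants, sprintf("st%02d", seq_len(n_strains)), calls)
}

# Table of pooled susceptibility counts from the published strain screen
# (affected / tested, pooled over doses), with the reference strain's
# pooled counts; used to check the exact test against printed p-values.
published_screen_counts <- function() {
  data.frame(
    strain = c("BPL/1 J", "JF1/MsJ", "PWD/PhJ", "SKIVE/EiJ", "AKR/J",
               "MOLD/EiJ", "CAST/EiJ", "MSM/Ms"),
    affected = c(5L, 4L, 5L, 3L, 1L, 5L, 1L, 0L),
    tested = c(6L, 6L, 7L, 15L, 7L, 6L, 9L, 6L),
    p_printed = c(0.0005, 0.004, 0.001, 0.2, 0.4, 0.0005, 0.4, 1.0),
    stringsAsFactors = FALSE)
}

# Published backcross linkage table: per-marker 2x2 counts
# (affected Ho, affected He, unaffected Ho, unaffected He) with the
# printed chi-square (1 dp) and p-value (3 sf).
published_linkage_counts <- function() {
  data.frame(
    marker_id = c("rs36385580", "rs38650989", "D6Mit186", "D6Mit102",
                  "D6Mit65", "D6Mit149", "rs31698248", "D6Mit254",
                  "rs30853093", "rs30662734", "rs36868180", "D6Mit135"),
    pos = c(59353905, 72592521, 73387511, 93463949, 101387523,
            106005405, 120207163, 125356646, 125365703, 125370997,
            127629804, 128834894),
    a_ho = c(28, 28, 30, 25, 25, 27, 26, 26, 26, 26, 27, 27),
    a_he = c(52, 52, 53, 58, 58, 56, 56, 56, 57, 57, 56, 56),
    u_ho = c(65, 66, 66, 66, 68, 68, 69, 66, 65, 65, 65, 63),
    u_he = c(20, 19, 19, 19, 17, 17, 16, 19, 20, 20, 20, 22),
    chi2_printed = c(28.8, 30.6, 29.5, 38.2, 42.3, 38.5, 41.6, 35.6,
                     34.5, 34.5, 32.7, 29.2),
    p_printed = c(7.95e-08, 3.21e-08, 5.49e-08, 6.36e-10, 7.92e-11,
                  5.44e-10, 1.09e-10, 2.42e-09, 4.32e-09, 4.32e-09,
                  1.06e-08, 6.53e-08),
    stringsAsFactors = FALSE)
}

# brute-force two-sided Fisher p by direct hypergeometric enumeration
# (explicit choose() products, independent of the log-space path)
brute_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- choose(c1, support) * choose(c2, r1 - support) /
    choose(n, r1)
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# brute-force Viterbi: enumerate all k^m state paths
brute_viterbi_score <- function(target, panel, params) {
  m <- length(target); k <- ncol(panel)
  le <- matrix(0, m, k)
  for (j in seq_len(k)) {
    both <- !is.na(target) & !is.na(panel[, j])
    le[both, j] <- ifelse(target[both] == panel[both, j],
                          log1p(-params$epsilon), log(params$epsilon))
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  sc <- rep(log(1 / k), nrow(paths))
  for (t in seq_len(m))
    sc <- sc + le[cbind(rep(t, nrow(paths)), paths[, t])]
  if (m > 1)
    for (t in seq_len(m - 1))
      sc <- sc + ifelse(paths[, t] == paths[, t + 1],
                        log1p(-params$tau), log(params$tau / (k - 1)))
  list(max = max(sc),
       n_opt = sum(sc > max(sc) - 1e-12),
       path = paths[which.max(sc), ])
}

# direct multivariate-normal log-density oracle for the mixed model
mvn_loglik <- function(y, X, beta, sigma_g2, sigma_e2, K) {
  n <- length(y)
  S <- sigma_g2 * K + sigma_e2 * diag(n)
  r <- y - X %*% beta
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(S)$modulus) +
            drop(t(r) %*% solve(S, r)))
}

# adjusted Rand index (for planted-partition recovery)
rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  agree <- (choose(n, 2) + sum(tab^2) -
              0.5 * (sum(rowSums(tab)^2) + sum(colSums(tab)^2)))
  agree / choose(n, 2)
}
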