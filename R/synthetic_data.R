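# Synthetic-data generators.
#
# These emulate the statistical structure the analysis stages assume:
# group-structured inbred panels with strain-biased missingness, a
# two-locus complementation model for binary susceptibility, backcross
# meiosis under the Haldane map function, and weighted gene networks with
# planted functional modules. Every generator is a pure function of
# (config, seed): the seed is mandatory and no global random state leaks.

#' Configuration for simulating a structured inbred strain panel
#'
#' Strains fall into groups (emulating mouse family groups); within each
#' ancestral haplotype block every group draws its own haplotype, so
#' strains of a group share blocks while groups diverge. Missingness is
#' applied per strain at a rate drawn from `missing_rate_range`,
#' emulating the strain-biased SNP coverage of merged strain databases.
#'
#' @param n_groups Number of strain groups.
#' @param strains_per_group Strains per group.
#' @param n_snps Number of SNPs simulated.
#' @param chrom_length Chromosome length in basepairs.
#' @param block_length Ancestral haplotype block length in basepairs.
#' @param between_group_divergence Per-SNP probability that a group's block
#'   haplotype differs from the ancestral allele.
#' @param within_group_diversity Per-SNP probability of a strain-private
#'   difference from its group haplotype.
#' @param missing_rate_range Length-2 interval; each strain's missing rate
#'   is drawn uniformly from it.
#' @param chrom Chromosome name used for all variants.
#' @param seed Integer seed (mandatory).
#' @return List of class `panel_sim_config`.
#' @export
panel_sim_config <- function(n_groups = 5, strains_per_group = 10,
                             n_snps = 1000, chrom_length = 70e6,
                             block_length = 5e6,
                             between_group_divergence = 0.3,
                             within_group_diversity = 0.02,
                             missing_rate_range = c(0.05, 0.20),
                             chrom = "chr6", seed) {
  if (missing(seed)) stop("panel_sim_config requires an explicit seed")
  probs <- c(between_group_divergence, within_group_diversity,
             missing_rate_range)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (n_snps < 1) stop("n_snps must be >= 1")
  if (block_length <= 0) stop("block_length must be positive")
  if (length(missing_rate_range) != 2L ||
      missing_rate_range[1] > missing_rate_range[2])
    stop("missing_rate_range must be an ordered length-2 interval")
  structure(list(n_groups = n_groups,
                 strains_per_group = strains_per_group, n_snps = n_snps,
                 chrom_length = chrom_length, block_length = block_length,
                 between_group_divergence = between_group_divergence,
                 within_group_diversity = within_group_diversity,
                 missing_rate_range = missing_rate_range, chrom = chrom,
                 seed = as.integer(seed)),
            class = "panel_sim_config")
}

#' Simulate a group-structured inbred strain genotype panel
#'
#' @param config A [panel_sim_config()].
#' @return A [genotype_matrix()] with a `groups` attribute (named character
#'   vector mapping strain to group).
#' @export
simulate_strain_panel <- function(config) {
  stopifnot(inherits(config, "panel_sim_config"))
  withr::with_seed(config$seed, {
    n_strains <- config$n_groups * config$strains_per_group
    pos <- sort(sample.int(config$chrom_length, config$n_snps))
    block <- (pos - 1L) %/% config$block_length
    calls <- matrix(0L, config$n_snps, n_strains)
    col <- 0L
    groups <- character(n_strains)
    for (g in seq_len(config$n_groups)) {
      # one haplotype per (group, block): flip from the ancestral allele
      grp_hap <- integer(config$n_snps)
      for (b in unique(block)) {
        idx <- which(block == b)
        grp_hap[idx] <- stats::rbinom(length(idx), 1L,
                                      config$between_group_divergence)
      }
      for (s in seq_len(config$strains_per_group)) {
        col <- col + 1L
        flip <- stats::rbinom(config$n_snps, 1L,
                              config$within_group_diversity)
        calls[, col] <- as.integer(xor(grp_hap, flip))
        groups[col] <- paste0("G", g)
      }
    }
    strains <- paste0(groups, "_S", rep(seq_len(config$strains_per_group),
                                        config$n_groups))
    rates <- stats::runif(n_strains, config$missing_rate_range[1],
                          config$missing_rate_range[2])
    for (j in seq_len(n_strains)) {
      mask <- stats::runif(config$n_snps) < rates[j]
      calls[mask, j] <- NA_integer_
    }
    poly <- apply(calls, 1L, function(x) length(unique(stats::na.omit(x))))
    if (all(poly < 2L))
      stop("no polymorphic SNPs simulated; increase ",
           "between_group_divergence or within_group_diversity")
    variants <- data.frame(snp_id = sprintf("snp%05d", seq_along(pos)),
                           chrom = config$chrom, pos = pos,
                           ref = "A", alt = "G",
                           stringsAsFactors = FALSE)
    gm <- genotype_matrix(variants, strains, calls)
    attr(gm, "groups") <- stats::setNames(groups, strains)
    gm
  })
}

#' Two-locus complementation trait model
#'
#' Binary susceptibility under a dominant primary allele `s`, with a
#' resistant primary allele `r` rescued by a dominant enhancer allele `E`.
#' A functional primary locus is required: primary-knockout animals are
#' never susceptible. Susceptible genotypes express the phenotype with
#' probability `penetrance`.
#'
#' @param primary_locus_pos,enhancer_locus_pos Basepair positions of the
#'   two loci on the simulated chromosome.
#' @param penetrance Probability in (0, 1] of expressing the phenotype
#'   given a susceptible genotype.
#' @return List of class `two_locus_trait_model`.
#' @export
two_locus_trait_model <- function(primary_locus_pos, enhancer_locus_pos,
                                  penetrance = 0.9) {
  if (penetrance <= 0 || penetrance > 1)
    stop("penetrance must lie in (0, 1]")
  structure(list(primary_locus_pos = primary_locus_pos,
                 enhancer_locus_pos = enhancer_locus_pos,
                 penetrance = penetrance),
            class = "two_locus_trait_model")
}

#' Susceptibility probability under the complementation rule
#'
#' For inbred strains pass one allele per locus; for crosses pass both.
#' Primary alleles are "s" (susceptible), "r" (resistant, functional) or
#' "ko" (knockout, non-functional); enhancer alleles are "E" or "e".
#'
#' @param primary Character vector of primary-locus alleles carried.
#' @param enhancer Character vector of enhancer-locus alleles carried.
#' @param penetrance Penetrance of the susceptible genotype.
#' @return Probability that the animal is affected.
#' @export
susceptibility_prob <- function(primary, enhancer, penetrance) {
  stopifnot(all(primary %in% c("s", "r", "ko")),
            all(enhancer %in% c("E", "e")))
  if (!any(primary %in% c("s", "r"))) return(0)       # knockout only
  if (any(primary == "s")) return(penetrance)         # dominant s
  if (any(enhancer == "E")) return(penetrance)        # r rescued by E
  0
}

#' Embed trait alleles into a simulated panel
#'
#' Labels each strain with primary and enhancer alleles according to a
#' per-group plan and inserts two genotype columns at the trait loci
#' (primary: 1 = s, 0 = r/knockout; enhancer: 1 = E, 0 = e) so that
#' association scans can rediscover them.
#'
#' @param panel A [simulate_strain_panel()] result (needs the `groups`
#'   attribute).
#' @param model A [two_locus_trait_model()].
#' @param group_alleles data.frame with columns `group`, `primary`
#'   ("s"/"r"/"ko") and `enhancer` ("E"/"e").
#' @return The panel with two extra variants (`trait_primary`,
#'   `trait_enhancer`) and attributes `trait_alleles` (per-strain labels)
#'   and `trait_model`.
#' @export
assign_trait_alleles <- function(panel, model, group_alleles) {
  stopifnot(inherits(panel, "genotype_matrix"),
            inherits(model, "two_locus_trait_model"))
  groups <- attr(panel, "groups")
  if (is.null(groups)) stop("panel lacks a 'groups' attribute")
  ga <- as.data.frame(group_alleles, stringsAsFactors = FALSE)
  stopifnot(all(c("group", "primary", "enhancer") %in% names(ga)))
  if (!all(groups %in% ga$group))
    stop("group_alleles must cover every panel group")
  idx <- match(groups, ga$group)
  labels <- data.frame(strain = panel$strains,
                       primary = ga$primary[idx],
                       enhancer = ga$enhancer[idx],
                       stringsAsFactors = FALSE)
  prim_call <- as.integer(labels$primary == "s")
  enh_call <- as.integer(labels$enhancer == "E")
  variants <- rbind(panel$variants,
                    data.frame(snp_id = c("trait_primary", "trait_enhancer"),
                               chrom = panel$variants$chrom[1L],
                               pos = c(model$primary_locus_pos,
                                       model$enhancer_locus_pos),
                               ref = "A", alt = "G",
                               stringsAsFactors = FALSE))
  calls <- rbind(panel$calls, prim_call, enh_call)
  out <- genotype_matrix(variants, panel$strains, calls)
  attr(out, "groups") <- groups
  attr(out, "trait_alleles") <- labels
  attr(out, "trait_model") <- model
  out
}

#' Simulate a dose-response susceptibility screen
#'
#' Each strain is challenged at each dose with `animals_per_dose` animals;
#' affected counts are Binomial with the strain's susceptibility
#' probability (penetrance for susceptible genotypes, `background` for
#' resistant ones).
#'
#' @param panel Annotated panel from [assign_trait_alleles()].
#' @param doses Numeric vector of doses (mg/kg).
#' @param animals_per_dose Animals tested per (strain, dose).
#' @param seed Integer seed.
#' @param background Affected probability for resistant genotypes.
#' @return A [dose_response_table()].
#' @export
simulate_dose_response <- function(panel, doses, animals_per_dose, seed,
                                   background = 0) {
  labels <- attr(panel, "trait_alleles")
  model <- attr(panel, "trait_model")
  if (is.null(labels) || is.null(model))
    stop("panel must come from assign_trait_alleles()")
  withr::with_seed(seed, {
    rows <- expand.grid(strain = labels$strain, dose = doses,
                        stringsAsFactors = FALSE)
    rows <- rows[order(match(rows$strain, labels$strain), rows$dose), ]
    i <- match(rows$strain, labels$strain)
    p <- vapply(i, function(k)
      susceptibility_prob(labels$primary[k], labels$enhancer[k],
                          model$penetrance), 0)
    p[p == 0] <- background
    rows$tested <- animals_per_dose
    rows$affected <- stats::rbinom(nrow(rows), animals_per_dose, p)
    dose_response_table(rows)
  })
}

#' Configuration for backcross simulation
#'
#' @param n_animals Cohort size.
#' @param marker_pos Sorted basepair positions of the genotyped markers.
#' @param cm_per_mb Recombination rate used to convert physical to genetic
#'   distance (centiMorgans per megabase; 0.5 is a standard mouse-scale
#'   value). Haldane's map function (no interference) converts distance to
#'   recombination fraction: r = (1 - exp(-2d)) / 2 with d in Morgans.
#' @param geno_missing_rate Per-genotype missingness rate.
#' @param chrom Chromosome name.
#' @param seed Integer seed (mandatory).
#' @return List of class `backcross_sim_config`.
#' @export
backcross_sim_config <- function(n_animals, marker_pos, cm_per_mb = 0.5,
                                 geno_missing_rate = 0, chrom = "chr6",
                                 seed) {
  if (missing(seed)) stop("backcross_sim_config requires an explicit seed")
  if (n_animals < 1) stop("n_animals must be >= 1")
  if (is.unsorted(marker_pos, strictly = TRUE))
    stop("marker_pos must be strictly increasing")
  structure(list(n_animals = as.integer(n_animals),
                 marker_pos = marker_pos, cm_per_mb = cm_per_mb,
                 geno_missing_rate = geno_missing_rate, chrom = chrom,
                 seed = as.integer(seed)),
            class = "backcross_sim_config")
}

#' Haldane recombination fraction between two physical positions
#'
#' @param d_bp Distance in basepairs.
#' @param cm_per_mb centiMorgans per megabase.
#' @return Recombination fraction in [0, 0.5).
#' @export
haldane_r <- function(d_bp, cm_per_mb) {
  morgans <- d_bp / 1e6 * cm_per_mb / 100
  (1 - exp(-2 * morgans)) / 2
}

#' Simulate a backcross cohort segregating a two-locus trait
#'
#' Each animal carries one recurrent-parent gamete and one F1 gamete
#' generated by a Markov recombination walk along the chromosome
#' (Haldane map function, no interference). Marker genotypes are `He`
#' where the F1 gamete carries the donor allele and `Ho` otherwise.
#' Phenotypes follow the complementation rule applied to the diploid
#' genotype at the two trait loci.
#'
#' @param config A [backcross_sim_config()].
#' @param model A [two_locus_trait_model()]; both loci must lie on the
#'   simulated chromosome.
#' @param parental_alleles List with elements `recurrent` and `donor`,
#'   each a list with `primary` and `enhancer` alleles. The default
#'   emulates a (resistant x resistant-with-enhancer) x resistant cross.
#' @return A [backcross_cohort()] with attribute `truth` holding each
#'   animal's F1-gamete origin ("R" recurrent / "D" donor) at every locus.
#' @export
simulate_backcross <- function(config, model,
                               parental_alleles = list(
                                 recurrent = list(primary = "r",
                                                  enhancer = "e"),
                                 donor = list(primary = "r",
                                              enhancer = "E"))) {
  stopifnot(inherits(config, "backcross_sim_config"),
            inherits(model, "two_locus_trait_model"))
  withr::with_seed(config$seed, {
    loci <- sort(unique(c(config$marker_pos, model$primary_locus_pos,
                          model$enhancer_locus_pos)))
    n_loci <- length(loci)
    r <- haldane_r(diff(loci), config$cm_per_mb)
    origin <- matrix("R", config$n_animals, n_loci)
    for (a in seq_len(config$n_animals)) {
      state <- sample(c("R", "D"), 1L)
      origin[a, 1L] <- state
      if (n_loci > 1L) {
        switch_ <- stats::runif(n_loci - 1L) < r
        for (k in seq_len(n_loci - 1L)) {
          if (switch_[k]) state <- if (state == "R") "D" else "R"
          origin[a, k + 1L] <- state
        }
      }
    }
    rec <- parental_alleles$recurrent
    don <- parental_alleles$donor
    ip <- match(model$primary_locus_pos, loci)
    ie <- match(model$enhancer_locus_pos, loci)
    prob <- vapply(seq_len(config$n_animals), function(a) {
      f1_prim <- if (origin[a, ip] == "D") don$primary else rec$primary
      f1_enh <- if (origin[a, ie] == "D") don$enhancer else rec$enhancer
      susceptibility_prob(c(rec$primary, f1_prim),
                          c(rec$enhancer, f1_enh), model$penetrance)
    }, 0)
    affected <- stats::runif(config$n_animals) < prob
    im <- match(config$marker_pos, loci)
    geno <- ifelse(origin[, im, drop = FALSE] == "D", "He", "Ho")
    if (config$geno_missing_rate > 0) {
      mask <- matrix(stats::runif(length(geno)) < config$geno_missing_rate,
                     nrow = nrow(geno))
      geno[mask] <- NA_character_
    }
    animals <- data.frame(
      animal_id = sprintf("bc%04d", seq_len(config$n_animals)),
      phenotype = ifelse(affected, "affected", "unaffected"),
      stringsAsFactors = FALSE)
    marker_map <- data.frame(
      marker_id = sprintf("m%03d", seq_along(config$marker_pos)),
      chrom = config$chrom, pos = config$marker_pos,
      stringsAsFactors = FALSE)
    bc <- backcross_cohort(animals, marker_map, geno)
    attr(bc, "truth") <- list(loci = loci, origin = origin)
    bc
  })
}

#' Configuration for planted-module network simulation
#'
#' Edge weights are Beta-distributed: within planted modules with mean
#' `within_weight_mean`, elsewhere with mean `between_weight_mean`, both
#' with the same concentration (shape1 + shape2). `concentration = Inf`
#' gives constant weights equal to the mean.
#'
#' @param n_genes Number of network genes.
#' @param module_sizes Integer vector of planted-module sizes
#'   (sum <= n_genes).
#' @param within_weight_mean,between_weight_mean Beta means in [0, 1];
#'   planted signal requires within > between.
#' @param weight_concentration Positive Beta concentration.
#' @param seed Integer seed (mandatory).
#' @return List of class `network_sim_config`.
#' @export
network_sim_config <- function(n_genes = 300, module_sizes = c(30, 30),
                               within_weight_mean = 0.6,
                               between_weight_mean = 0.1,
                               weight_concentration = 20, seed) {
  if (missing(seed)) stop("network_sim_config requires an explicit seed")
  if (sum(module_sizes) > n_genes)
    stop("sum(module_sizes) must be <= n_genes")
  if (weight_concentration <= 0)
    stop("weight_concentration must be positive")
  means <- c(within_weight_mean, between_weight_mean)
  if (any(means < 0 | means > 1)) stop("weight means must lie in [0, 1]")
  structure(list(n_genes = as.integer(n_genes),
                 module_sizes = as.integer(module_sizes),
                 within_weight_mean = within_weight_mean,
                 between_weight_mean = between_weight_mean,
                 weight_concentration = weight_concentration,
                 seed = as.integer(seed)),
            class = "network_sim_config")
}

rbeta_mean <- function(n, mean, conc) {
  if (mean <= 0) return(rep(0, n))
  if (mean >= 1) return(rep(1, n))
  if (!is.finite(conc)) return(rep(mean, n))
  stats::rbeta(n, mean * conc, (1 - mean) * conc)
}

#' Simulate a functional network with planted gene modules
#'
#' @param config A [network_sim_config()].
#' @return A [functional_network()] with attribute `modules`: a named list
#'   of planted member gene_ids.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "network_sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    genes <- sprintf("gene%04d", seq_len(n))
    membership <- rep(0L, n)
    at <- 1L
    for (m in seq_along(config$module_sizes)) {
      membership[at:(at + config$module_sizes[m] - 1L)] <- m
      at <- at + config$module_sizes[m]
    }
    w <- matrix(0, n, n)
    ut <- which(upper.tri(w), arr.ind = TRUE)
    within <- membership[ut[, 1L]] != 0L &
      membership[ut[, 1L]] == membership[ut[, 2L]]
    vals <- numeric(nrow(ut))
    vals[within] <- rbeta_mean(sum(within), config$within_weight_mean,
                               config$weight_concentration)
    vals[!within] <- rbeta_mean(sum(!within), config$between_weight_mean,
                                config$weight_concentration)
    w[upper.tri(w)] <- vals
    w <- w + t(w)
    net <- functional_network(genes, w)
    modules <- lapply(seq_along(config$module_sizes), function(m)
      genes[membership == m])
    names(modules) <- paste0("module", seq_along(modules))
    attr(net, "modules") <- modules
    net
  })
}
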