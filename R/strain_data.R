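# Core domain containers and file formats.
#
# Conventions used throughout the package:
#   * genotype calls are haploid-coded (0 = reference allele, 1 = alternate
#     allele, NA = missing) because all panel strains are inbred and hence
#     homozygous; heterozygous diploid input is treated as missing.
#   * SNP/marker positions are 1-based basepairs (VCF/TSV convention);
#     gene intervals are 0-based half-open (BED convention).
#   * result files start with a single '#'-prefixed provenance line.

#' Construct a strain-by-SNP genotype matrix
#'
#' @param variants data.frame with columns `snp_id`, `chrom`, `pos`, `ref`,
#'   `alt`; one row per SNP. Positions are 1-based.
#' @param strains Character vector of strain names (case-sensitive keys;
#'   slashes and spaces are allowed).
#' @param calls Integer matrix (`nrow(variants)` x `length(strains)`) of
#'   haploid calls: 0 = ref, 1 = alt, NA = missing.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(variants, strains, calls) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  needed <- c("snp_id", "chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(variants)))
    stop("variants must have columns: ", paste(needed, collapse = ", "))
  variants <- variants[needed]
  variants$pos <- as.integer(variants$pos)
  strains <- as.character(strains)
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != nrow(variants) || ncol(calls) != length(strains))
    stop("calls must be ", nrow(variants), " x ", length(strains))
  if (anyDuplicated(variants$snp_id))
    stop("duplicate snp_id: ",
         paste(unique(variants$snp_id[duplicated(variants$snp_id)]),
               collapse = ", "))
  if (any(variants$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt))
    stop("ref and alt alleles must differ")
  bad <- !(calls %in% c(0L, 1L, NA_integer_))
  if (any(bad)) stop("calls must be 0, 1 or NA")
  ord <- order(variants$chrom, variants$pos)
  if (is.unsorted(ord) && !identical(ord, seq_len(nrow(variants)))) {
    variants <- variants[ord, , drop = FALSE]
    calls <- calls[ord, , drop = FALSE]
  }
  rownames(variants) <- NULL
  dimnames(calls) <- list(variants$snp_id, strains)
  structure(list(variants = variants, strains = strains, calls = calls),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d SNPs x %d strains (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Read a genotype matrix from the canonical TSV dialect
#'
#' The dialect is tab-separated with header
#' `chrom pos snp_id ref alt <strain...>`, calls in `{0, 1, NA}`, and an
#' optional leading `#` provenance line. Reading is gzip-transparent.
#' Variants arriving out of positional order are sorted with a warning.
#'
#' @param path Path to a `.tsv` or `.tsv.gz` file.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[!startsWith(lines, "#")]
  if (length(lines) < 1L) stop("empty genotype file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  fixed <- c("chrom", "pos", "snp_id", "ref", "alt")
  if (length(header) < 6L || !identical(header[1:5], fixed))
    stop("genotype TSV header must start with: ",
         paste(fixed, collapse = " "))
  strains <- header[-(1:5)]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nfield <- length(header)
  for (i in seq_along(body))
    if (length(body[[i]]) != nfield)
      stop("line ", i + 1L, ": expected ", nfield, " fields, got ",
           length(body[[i]]))
  m <- do.call(rbind, body)
  if (is.null(m)) stop("genotype file has no variant rows: ", path)
  callchr <- m[, -(1:5), drop = FALSE]
  badm <- matrix(!(callchr %in% c("0", "1", "NA")),
                 nrow = nrow(callchr))
  bad <- which(badm, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("line ", bad[1L, 1L] + 1L, ": invalid call symbol '",
         callchr[bad[1L, 1L], bad[1L, 2L]], "' (must be 0, 1 or NA)")
  calls <- matrix(suppressWarnings(as.integer(callchr)),
                  nrow = nrow(callchr))
  variants <- data.frame(snp_id = m[, 3L], chrom = m[, 1L],
                         pos = as.integer(m[, 2L]), ref = m[, 4L],
                         alt = m[, 5L], stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos)
  if (!identical(ord, seq_len(nrow(variants))))
    warning("variants in ", path, " were not position-sorted; sorting")
  genotype_matrix(variants, strains, calls)
}

#' Write a genotype matrix in the canonical TSV dialect
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param seed,config_hash Optional provenance fields recorded in the `#`
#'   header line.
#' @export
write_genotype_tsv <- function(gm, path, seed = NA, config_hash = NA) {
  stopifnot(inherits(gm, "genotype_matrix"))
  v <- gm$variants
  callchr <- matrix(as.character(gm$calls), nrow = nrow(gm$calls))
  callchr[is.na(callchr)] <- "NA"
  header <- paste(c("chrom", "pos", "snp_id", "ref", "alt", gm$strains),
                  collapse = "\t")
  rows <- paste(v$chrom, v$pos, v$snp_id, v$ref, v$alt,
                apply(callchr, 1L, paste, collapse = "\t"), sep = "\t")
  if (nrow(v) == 0L) rows <- character(0)
  writeLines(c(provenance_line(seed, config_hash), header, rows), path)
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Haploid or homozygous-diploid GT fields map onto the haploid coding
#' (`0/0` -> 0, `1/1` -> 1, `./.` -> NA). Heterozygous calls violate the
#' inbred-strain assumption and become NA with a warning; multi-allelic
#' records are skipped with a warning.
#'
#' @param path Path to a VCF file.
#' @return A [genotype_matrix()]; sample names become strain names.
#' @export
read_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("read_vcf requires the vcfR package")
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped")
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  calls <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  calls[gt %in% c("0", "0/0")] <- 0L
  calls[gt %in% c("1", "1/1")] <- 1L
  het <- gt %in% c("0/1", "1/0")
  if (any(het))
    warning(sum(het), " heterozygous call(s) set to missing ",
            "(inbred-strain assumption)")
  ids <- fix[, "ID"]
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix[blank, "CHROM"], ":", fix[blank, "POS"])
  variants <- data.frame(snp_id = ids, chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         stringsAsFactors = FALSE)
  genotype_matrix(variants, colnames(gt), calls)
}

#' Construct / read a per-strain dose-response count table
#'
#' Rows are (strain, dose in mg/kg, affected, tested); `(strain, dose)`
#' pairs must be unique and `0 <= affected <= tested`.
#'
#' @param df data.frame with columns `strain`, `dose`, `affected`, `tested`.
#' @return data.frame of class `dose_response_table`.
#' @export
dose_response_table <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  needed <- c("strain", "dose", "affected", "tested")
  if (!all(needed %in% names(df)))
    stop("need columns: ", paste(needed, collapse = ", "))
  df <- df[needed]
  if (any(df$dose <= 0)) stop("doses must be positive")
  if (any(df$affected < 0 | df$affected > df$tested))
    stop("need 0 <= affected <= tested")
  if (anyDuplicated(df[c("strain", "dose")]))
    stop("duplicate (strain, dose) rows")
  class(df) <- c("dose_response_table", "data.frame")
  df
}

#' @rdname dose_response_table
#' @param path TSV file with the four columns above.
#' @export
read_dose_response_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  dose_response_table(df)
}

#' Construct a backcross cohort
#'
#' @param animals data.frame with `animal_id` and `phenotype`
#'   ("affected"/"unaffected").
#' @param marker_map data.frame with `marker_id`, `chrom`, `pos`; positions
#'   strictly increasing within a chromosome.
#' @param genotypes Character matrix (animals x markers) over
#'   `{"Ho", "He", NA}` — Ho = homozygous recurrent-parent allele,
#'   He = heterozygous.
#' @return Object of class `backcross_cohort`.
#' @export
backcross_cohort <- function(animals, marker_map, genotypes) {
  animals <- as.data.frame(animals, stringsAsFactors = FALSE)
  marker_map <- as.data.frame(marker_map, stringsAsFactors = FALSE)
  genotypes <- as.matrix(genotypes)
  stopifnot(all(c("animal_id", "phenotype") %in% names(animals)),
            all(c("marker_id", "chrom", "pos") %in% names(marker_map)))
  if (!all(animals$phenotype %in% c("affected", "unaffected")))
    stop("phenotype must be 'affected' or 'unaffected'")
  if (nrow(genotypes) != nrow(animals) ||
      ncol(genotypes) != nrow(marker_map))
    stop("genotypes must be n_animals x n_markers")
  if (!all(genotypes %in% c("Ho", "He", NA_character_)))
    stop("genotypes must be 'Ho', 'He' or NA")
  for (ch in unique(marker_map$chrom)) {
    p <- marker_map$pos[marker_map$chrom == ch]
    if (any(diff(p) <= 0))
      stop("marker positions must be strictly increasing on ", ch)
  }
  dimnames(genotypes) <- list(animals$animal_id, marker_map$marker_id)
  structure(list(animals = animals, marker_map = marker_map,
                 genotypes = genotypes), class = "backcross_cohort")
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>gene...`.
#' Duplicate genes within a set or duplicate set names are rejected.
#'
#' @param path Path to a `.gmt` file.
#' @return Named list of character vectors (class `gene_set_collection`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 1L) < 3L
  if (any(short))
    stop("GMT line ", which(short)[1L], ": fewer than 3 fields")
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("duplicate gene-set names")
  dup <- vapply(sets, anyDuplicated, 1L) > 0L
  if (any(dup))
    stop("duplicate gene within set(s): ",
         paste(names(sets)[dup], collapse = ", "))
  structure(sets, class = "gene_set_collection")
}

#' Read gene models from a BED file (BED3+name)
#'
#' BED intervals are 0-based half-open; they are kept in that convention.
#'
#' @param path Path to a BED file with at least 4 columns
#'   (chrom, start, end, gene_id).
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED file must have >= 4 columns (BED3+name)")
  out <- data.frame(gene_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]),
                    end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end))
    stop("BED interval with start >= end at line ",
         which(out$start >= out$end)[1L])
  out
}

#' Construct a weighted functional gene network
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param weights Symmetric numeric matrix with entries in `[0, 1]` and a
#'   zero diagonal.
#' @return Object of class `functional_network`.
#' @export
functional_network <- function(gene_ids, weights) {
  gene_ids <- as.character(gene_ids)
  weights <- as.matrix(weights)
  if (nrow(weights) != length(gene_ids) ||
      ncol(weights) != length(gene_ids))
    stop("weights must be square over gene_ids")
  if (any(weights < 0 | weights > 1)) stop("weights must lie in [0, 1]")
  if (any(abs(weights - t(weights)) > 1e-12))
    stop("weight matrix must be symmetric")
  diag(weights) <- 0
  dimnames(weights) <- list(gene_ids, gene_ids)
  structure(list(gene_ids = gene_ids, weights = weights),
            class = "functional_network")
}

#' Read a weighted edge list into a functional network
#'
#' Expects tab-separated `gene_a gene_b weight` rows; weights must lie in
#' `[0, 1]` and re-stated edges must agree.
#'
#' @param path Path to the edge-list TSV.
#' @return A [functional_network()].
#' @export
read_network_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("edge list needs 3 columns: gene_a gene_b weight")
  names(df)[1:3] <- c("a", "b", "w")
  if (any(df$w < 0 | df$w > 1))
    stop("edge weight outside [0, 1] at line ",
         which(df$w < 0 | df$w > 1)[1L])
  genes <- sort(unique(c(df$a, df$b)))
  w <- matrix(0, length(genes), length(genes),
              dimnames = list(genes, genes))
  seen <- matrix(FALSE, length(genes), length(genes))
  ia <- match(df$a, genes); ib <- match(df$b, genes)
  for (k in seq_len(nrow(df))) {
    i <- ia[k]; j <- ib[k]
    if (seen[i, j] && abs(w[i, j] - df$w[k]) > 1e-12)
      stop("conflicting duplicate edge ", df$a[k], " - ", df$b[k])
    w[i, j] <- w[j, i] <- df$w[k]
    seen[i, j] <- seen[j, i] <- TRUE
  }
  functional_network(genes, w)
}

#' Write a ranked gene-score table
#'
#' Emits a provenance header, a fixed column order, and rows ordered by
#' rank then gene_id so output is deterministic.
#'
#' @param table data.frame containing at least `gene_id` and `rank`.
#' @param path Output path.
#' @param seed,config_hash Provenance fields.
#' @export
write_score_table <- function(table, path, seed = NA, config_hash = NA) {
  stopifnot(all(c("gene_id", "rank") %in% names(table)))
  first <- c("gene_id", "rank")
  table <- table[c(first, setdiff(names(table), first))]
  table <- table[order(table$rank, table$gene_id), , drop = FALSE]
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(provenance_line(seed, config_hash), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
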