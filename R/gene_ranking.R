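# Final candidate ranking: SNP association scores are carried to genes
# (nearest gene within 1 Mb, max -log10 p over assigned SNPs) and summed
# with the functional -log10 FPR after scaling each component by its
# maximum over the positional candidates, giving the combined gene score
# s_cg in [0, 2].

#' Assign SNPs to their nearest gene within a window
#'
#' Each SNP goes to the single gene whose interval is nearest (distance 0
#' inside the gene, otherwise distance to the closer interval edge); SNPs
#' farther than `window` basepairs from every gene stay unassigned. Ties
#' go to the gene with the lower interval start.
#'
#' @param assoc data.frame with `snp_id`, `chrom`, `pos`, `p_value`
#'   (e.g. from [lrt_scan()]).
#' @param genes Gene models as from [read_bed()] (`gene_id`, `chrom`,
#'   `start`, `end`; 0-based half-open).
#' @param window Maximum assignment distance in basepairs (inclusive).
#' @return List with `assignments` (data.frame `snp_id`, `gene_id`,
#'   `distance`) and `unassigned` (character vector of snp_ids).
#' @export
assign_snps_to_genes <- function(assoc, genes, window = 1e6) {
  stopifnot(all(c("snp_id", "chrom", "pos") %in% names(assoc)),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  rows <- lapply(seq_len(nrow(assoc)), function(i) {
    g <- genes[genes$chrom == assoc$chrom[i], , drop = FALSE]
    if (nrow(g) == 0L)
      return(data.frame(snp_id = assoc$snp_id[i],
                        gene_id = NA_character_, distance = NA_real_,
                        stringsAsFactors = FALSE))
    pos <- assoc$pos[i]
    # gene occupies 1-based positions (start+1)..end
    dist <- pmax(0, g$start + 1L - pos, pos - g$end)
    best <- order(dist, g$start)[1L]
    data.frame(snp_id = assoc$snp_id[i], gene_id = g$gene_id[best],
               distance = dist[best], stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  ok <- !is.na(res$distance) & res$distance <= window
  list(assignments = res[ok, , drop = FALSE],
       unassigned = res$snp_id[!ok])
}

#' Per-gene association score from assigned SNPs
#'
#' The gene score is the maximum -log10 p-value over all SNPs assigned to
#' the gene; genes with no assigned SNP score 0.
#'
#' @param assoc data.frame with `snp_id` and `p_value`.
#' @param assignment A [assign_snps_to_genes()] result.
#' @param gene_ids Gene universe to report (all positional candidates).
#' @return Named numeric vector of -log10 p scores over `gene_ids`.
#' @export
gene_assoc_score <- function(assoc, assignment, gene_ids) {
  neglog <- -log10(assoc$p_value)
  names(neglog) <- assoc$snp_id
  score <- stats::setNames(numeric(length(gene_ids)), gene_ids)
  asn <- assignment$assignments
  asn <- asn[asn$gene_id %in% gene_ids, , drop = FALSE]
  if (nrow(asn)) {
    by_gene <- tapply(neglog[asn$snp_id], asn$gene_id, max)
    score[names(by_gene)] <- by_gene
  }
  score
}

#' Combine association and functional scores into the ranked gene table
#'
#' Each component is scaled by its maximum over the positional candidate
#' universe and the two scaled components summed:
#' s_cg = assoc/max(assoc) + func/max(func), so s_cg lies in [0, 2] and a
#' gene attaining both maxima scores exactly 2. An all-zero component is
#' set to 0 for every gene with a warning (no division by zero). The
#' table is sorted by s_cg descending, ties broken alphabetically.
#'
#' @param assoc_scores Named numeric vector (per-gene -log10 p).
#' @param func_scores Named numeric vector (per-gene -log10 FPR) over the
#'   same gene universe.
#' @return data.frame with `gene_id`, `assoc_neglog10p`,
#'   `func_neglog10fpr`, `s_cg`, `rank`.
#' @export
combined_score <- function(assoc_scores, func_scores) {
  genes <- names(assoc_scores)
  if (is.null(genes) || is.null(names(func_scores)))
    stop("score vectors must be named by gene_id")
  if (!setequal(genes, names(func_scores)))
    stop("score vectors must cover the same gene universe")
  func_scores <- func_scores[genes]
  if (any(assoc_scores < 0) || any(func_scores < 0))
    stop("component scores must be non-negative")
  scale_comp <- function(x, label) {
    m <- max(x)
    if (m == 0) {
      warning("all-zero ", label, " component; term set to 0")
      return(x)
    }
    x / m
  }
  s <- scale_comp(assoc_scores, "association") +
    scale_comp(func_scores, "functional")
  out <- data.frame(gene_id = genes, assoc_neglog10p = assoc_scores,
                    func_neglog10fpr = func_scores, s_cg = s,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$s_cg, out$gene_id), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
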