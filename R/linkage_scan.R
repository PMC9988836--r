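# Backcross linkage scan: per-marker Pearson chi-square test of genotype
# (Ho/He) against phenotype (affected/unaffected). No continuity
# correction and no multiple-testing adjustment: the scan reports raw
# per-marker statistics, as is conventional for small backcross marker
# panels.

#' Pearson chi-square test for a 2x2 table (no continuity correction)
#'
#' Uses the closed-form margin formula
#' chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d)) with a chi-square(1)
#' upper-tail p-value. A zero margin returns (0, 1) with a warning.
#'
#' @param a,b,c,d Cell counts: (affected Ho, affected He, unaffected Ho,
#'   unaffected He).
#' @return List with `chi2` and `p_value`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) {
    warning("zero margin: chi-square undefined, returning (0, 1)")
    return(list(chi2 = 0, p_value = 1))
  }
  n <- r1 + r2
  chi2 <- n * (a * d - b * c)^2 / (r1 * r2 * c1 * c2)
  list(chi2 = chi2,
       p_value = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Chi-square segregation scan over all markers of a backcross cohort
#'
#' For each marker, animals with a missing genotype at that marker are
#' dropped for that marker only (so per-marker totals may differ), and
#' the 2x2 table of phenotype by genotype is tested with
#' [chi_square_2x2()].
#'
#' @param cohort A [backcross_cohort()].
#' @return data.frame sorted by position with columns `marker_id`,
#'   `chrom`, `pos`, `a_ho`, `a_he`, `u_ho`, `u_he`, `n_used`, `chi2`,
#'   `p_value`.
#' @export
scan_markers <- function(cohort) {
  stopifnot(inherits(cohort, "backcross_cohort"))
  map <- cohort$marker_map
  if (nrow(map) < 1L) stop("cohort has no markers")
  affected <- cohort$animals$phenotype == "affected"
  rows <- lapply(seq_len(nrow(map)), function(j) {
    g <- cohort$genotypes[, j]
    use <- !is.na(g)
    a <- sum(affected[use] & g[use] == "Ho")
    b <- sum(affected[use] & g[use] == "He")
    cc <- sum(!affected[use] & g[use] == "Ho")
    dd <- sum(!affected[use] & g[use] == "He")
    res <- suppressWarnings(chi_square_2x2(a, b, cc, dd))
    data.frame(marker_id = map$marker_id[j], chrom = map$chrom[j],
               pos = map$pos[j], a_ho = a, a_he = b, u_ho = cc,
               u_he = dd, n_used = a + b + cc + dd, chi2 = res$chi2,
               p_value = res$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$pos), , drop = FALSE]
}
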