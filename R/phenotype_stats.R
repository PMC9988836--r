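# Strain susceptibility testing: dose pooling and exact contingency tests
# of each strain's pooled affected/tested counts against a reference
# strain. Dose is ignored in pooling (the screen asks only whether a
# strain is susceptible, not for a dose-response curve).

#' Pool affected/tested counts over all doses for one strain
#'
#' @param dr A [dose_response_table()].
#' @param strain Strain to pool.
#' @return List with `strain`, `affected`, `tested` and `percent_affected`
#'   (integer percent, rounded half away from zero).
#' @export
pool_doses <- function(dr, strain) {
  stopifnot(inherits(dr, "dose_response_table"))
  rows <- dr[dr$strain == strain, , drop = FALSE]
  if (nrow(rows) == 0L) stop("strain not present: ", strain)
  affected <- sum(rows$affected)
  tested <- sum(rows$tested)
  list(strain = strain, affected = affected, tested = tested,
       percent_affected = as.integer(round_half_up(100 * affected / tested)))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric enumeration in log space: with both margins
#' fixed, the two-sided p-value is the sum of the probabilities of all
#' admissible tables whose point probability does not exceed that of the
#' observed table (the point-probability method). A table with a zero
#' margin carries no information and returns p = 1 with a warning.
#'
#' @param a,b,c,d Cell counts, laid out as rows (group1: a, b),
#'   (group2: c, d).
#' @return Two-sided p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  if (r1 == 0L || r2 == 0L || c1 == 0L || c2 == 0L) {
    warning("zero margin: test is uninformative, p = 1")
    return(1)
  }
  n <- r1 + r2
  lo <- max(0L, c1 - r2)
  hi <- min(r1, c1)
  support <- lo:hi
  logp <- stats::dhyper(support, c1, c2, r1, log = TRUE)
  log_obs <- stats::dhyper(a, c1, c2, r1, log = TRUE)
  # tolerance guards against ties lost to floating-point noise
  keep <- logp <= log_obs + 1e-7
  p <- sum(exp(logp[keep]))
  min(p, 1)
}

#' Screen strains for susceptibility against a reference strain
#'
#' Pools each strain's counts over all doses and tests them against the
#' pooled reference counts with the two-sided Fisher exact test. Raw
#' p-values are reported alongside a display version rounded to one
#' significant figure (values below 1e-4 display as "<0.0001"), the
#' convention of published susceptibility tables.
#'
#' @param dr A [dose_response_table()].
#' @param reference_strain Strain against which all others are tested.
#' @return data.frame with columns `strain`, `affected`, `tested`,
#'   `percent_affected`, `p_value`, `p_display`.
#' @export
susceptibility_screen <- function(dr, reference_strain) {
  stopifnot(inherits(dr, "dose_response_table"))
  ref <- pool_doses(dr, reference_strain)
  strains <- setdiff(unique(dr$strain), reference_strain)
  rows <- lapply(strains, function(s) {
    pooled <- pool_doses(dr, s)
    p <- fisher_exact_two_sided(pooled$affected,
                                pooled$tested - pooled$affected,
                                ref$affected, ref$tested - ref$affected)
    data.frame(strain = s, affected = pooled$affected,
               tested = pooled$tested,
               percent_affected = pooled$percent_affected,
               p_value = p, p_display = format_p_display(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "reference_strain") <- reference_strain
  attr(out, "reference_counts") <- c(affected = ref$affected,
                                     tested = ref$tested)
  out
}
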