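#' @keywords internal
"_PACKAGE"

# Provenance header written at the top of every result/table file.  Kept
# deterministic (no timestamps) so that reruns are byte-identical.
provenance_line <- function(seed = NA, config_hash = NA) {
  sprintf("# strainscan %s | seed=%s | config=%s",
          as.character(utils::packageVersion("strainscan")),
          as.character(seed), as.character(config_hash))
}

# FNV-1a 32-bit hash over a character representation of an R object; used
# for config digests in run manifests (stable across sessions, no deps).
fnv1a_hash <- function(x) {
  s <- paste(utils::capture.output(dput(x)), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(h, b)
    # 32-bit modular multiply by the FNV prime 16777619
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

# Round half away from zero (the convention used by the phenotype tables;
# base round() rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' One-significant-figure p-value rounding, half away from zero
#'
#' Published susceptibility tables round p to one significant figure with
#' halves rounded up (e.g. an exact p of 0.35 prints as 0.4). Base
#' `signif()` rounds half to even on binary floats, so exact decimal
#' halves can round down; this version carries a relative guard so that
#' values within floating-point noise of a half round up.
#'
#' @param p p-value(s) in (0, 1].
#' @return Numeric vector rounded to one significant figure.
#' @export
round_p_display <- function(p) {
  vapply(p, function(x) {
    if (x <= 0) stop("p must be positive")
    e <- floor(log10(x) + 1e-12)
    floor(x / 10^e + 0.5 + 1e-9) * 10^e
  }, 0)
}

# display string used by the susceptibility tables
format_p_display <- function(p) {
  ifelse(p < 1e-4, "<0.0001",
         format(round_p_display(p), scientific = FALSE, trim = TRUE))
}

#' Bonferroni significance thresholds for an association scan
#'
#' Returns the stringent (Bonferroni, `0.05 / n_tests`) and moderate (fixed
#' `0.05`) p-value cut-offs reported alongside association scans.
#'
#' @param n_tests Number of statistical tests performed (positive integer).
#' @return Named list with `stringent` and `moderate` thresholds.
#' @examples
#' significance_thresholds(13257)
#' @export
significance_thresholds <- function(n_tests) {
  if (length(n_tests) != 1L || is.na(n_tests) || n_tests < 1)
    stop("n_tests must be a single positive integer")
  list(stringent = 0.05 / n_tests, moderate = 0.05)
}
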