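# HMM genotype imputation. Hidden states are reference strains (the
# candidates most concordant with the target); the decoded Viterbi path
# names, at every SNP, the reference strain whose haplotype the target is
# most plausibly copying, and missing target calls are filled from that
# strain. Decoding is fully deterministic.

#' HMM parameters for Viterbi imputation
#'
#' @param k Number of reference strains in the panel.
#' @param epsilon Per-SNP emission error probability (probability that an
#'   observed target call mismatches the copied reference call).
#' @param tau Per-interval state-switch probability, constant between
#'   adjacent SNPs.
#' @return List of class `hmm_params`.
#' @export
hmm_params <- function(k = 8L, epsilon = 0.01, tau = 0.002) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must lie in (0, 0.5)")
  if (tau <= 0 || tau >= 1) stop("tau must lie in (0, 1)")
  if (k < 1) stop("k must be >= 1")
  structure(list(k = as.integer(k), epsilon = epsilon, tau = tau),
            class = "hmm_params")
}

#' Rank candidate reference strains by concordance with a target
#'
#' Candidates are ordered by genotype concordance with the target over
#' jointly observed SNPs (ties broken lexicographically by strain name);
#' the top `k` are returned as the reference panel.
#'
#' @param gm A [genotype_matrix()].
#' @param target_strain Strain to be imputed (excluded from its panel).
#' @param k Panel size; if larger than the number of usable candidates,
#'   all are returned with a warning.
#' @return Character vector of reference strain names, best first, with a
#'   `concordance` attribute.
#' @export
select_reference_panel <- function(gm, target_strain, k) {
  stopifnot(inherits(gm, "genotype_matrix"),
            target_strain %in% gm$strains)
  t_calls <- gm$calls[, target_strain]
  cands <- setdiff(gm$strains, target_strain)
  conc <- vapply(cands, function(s) {
    both <- !is.na(t_calls) & !is.na(gm$calls[, s])
    if (!any(both)) return(NA_real_)
    mean(t_calls[both] == gm$calls[both, s])
  }, 0)
  if (anyNA(conc))
    stop("candidate(s) share no observed SNP with the target: ",
         paste(cands[is.na(conc)], collapse = ", "))
  ord <- order(-conc, cands)
  if (k > length(cands)) {
    warning("k = ", k, " exceeds the ", length(cands),
            " available candidates; using all")
    k <- length(cands)
  }
  sel <- cands[ord][seq_len(k)]
  structure(sel, concordance = conc[ord][seq_len(k)])
}

#' Viterbi decoding of a target strain against a reference panel
#'
#' Maximum-probability hidden-state path under a uniform initial
#' distribution, transition probabilities stay = 1 - tau and
#' switch = tau / (k - 1), and emissions 1 - epsilon (match), epsilon
#' (mismatch) or 1 (either call missing, uninformative). All computation
#' is in log space; ties break toward the lower state index.
#'
#' @param target_calls Integer vector of the target's calls (0/1/NA).
#' @param panel_calls Matrix (SNPs x k) of reference calls (0/1/NA).
#' @param params An [hmm_params()] (its `k` must match `ncol(panel_calls)`).
#' @return List of class `viterbi_path` with `state` (reference column
#'   index per SNP) and `log_score` (log joint probability of the path).
#' @export
viterbi_decode <- function(target_calls, panel_calls, params) {
  stopifnot(inherits(params, "hmm_params"))
  panel_calls <- as.matrix(panel_calls)
  m <- length(target_calls)
  k <- ncol(panel_calls)
  if (m < 1L) stop("need >= 1 SNP")
  if (nrow(panel_calls) != m)
    stop("panel_calls must have one row per target SNP")
  if (k != params$k)
    stop("panel has ", k, " strains but params$k = ", params$k)
  if (all(is.na(target_calls)))
    warning("target has no observed calls; path is uninformative")
  # log emission matrix (SNPs x states)
  le <- matrix(0, m, k)
  obs <- !is.na(target_calls)
  for (j in seq_len(k)) {
    both <- obs & !is.na(panel_calls[, j])
    le[both, j] <- ifelse(target_calls[both] == panel_calls[both, j],
                          log1p(-params$epsilon), log(params$epsilon))
  }
  if (k == 1L)
    return(structure(list(state = rep(1L, m),
                          log_score = sum(le[, 1L])),
                     class = "viterbi_path"))
  lstay <- log1p(-params$tau)
  lswitch <- log(params$tau / (k - 1))
  delta <- le[1L, ] + log(1 / k)
  back <- matrix(0L, m, k)
  for (t in seq_len(m - 1L) + 1L) {
    # from-state achieving the max for each to-state; stay vs best switch
    best_prev <- which.max(delta)             # lowest index wins ties
    score_stay <- delta + lstay
    score_switch <- delta[best_prev] + lswitch
    take_stay <- score_stay >= score_switch
    # when best_prev == j, "switch" from the runner-up instead
    runner <- which.max(replace(delta, best_prev, -Inf))
    from <- ifelse(take_stay, seq_len(k), best_prev)
    new_delta <- ifelse(take_stay, score_stay, score_switch)
    self <- !take_stay & seq_len(k) == best_prev
    if (any(self)) {
      alt <- delta[runner] + lswitch
      stay_self <- delta[best_prev] + lstay
      if (stay_self >= alt) {
        new_delta[self] <- stay_self
        from[self] <- best_prev
      } else {
        new_delta[self] <- alt
        from[self] <- runner
      }
    }
    delta <- new_delta + le[t, ]
    back[t, ] <- from
  }
  state <- integer(m)
  state[m] <- which.max(delta)
  if (m > 1L)
    for (t in rev(seq_len(m - 1L)))
      state[t] <- back[t + 1L, state[t + 1L]]
  structure(list(state = state, log_score = max(delta)),
            class = "viterbi_path")
}

#' Impute one strain's missing calls from its reference panel
#'
#' Selects the `params$k` most concordant reference strains, Viterbi-
#' decodes the target against them, and fills each missing target call
#' with the decoded reference strain's call at that SNP (staying missing
#' if the reference is missing there too). Observed calls are never
#' altered.
#'
#' @param gm A [genotype_matrix()].
#' @param target_strain Strain to impute.
#' @param params An [hmm_params()]; `k` is capped at the number of
#'   available candidates.
#' @return List with `calls` (the imputed call vector), `path` (the
#'   [viterbi_decode()] result), `panel` (reference strain names) and
#'   `report` (pre/post missing fractions).
#' @export
impute_strain <- function(gm, target_strain, params = hmm_params()) {
  panel <- suppressWarnings(
    select_reference_panel(gm, target_strain, params$k))
  k_eff <- length(panel)
  params_eff <- hmm_params(k_eff, params$epsilon, params$tau)
  target <- gm$calls[, target_strain]
  panel_calls <- gm$calls[, panel, drop = FALSE]
  path <- viterbi_decode(target, panel_calls, params_eff)
  out <- target
  fill <- which(is.na(target))
  if (length(fill))
    out[fill] <- panel_calls[cbind(fill, path$state[fill])]
  list(calls = out, path = path, panel = panel,
       report = list(pre_missing = mean(is.na(target)),
                     post_missing = mean(is.na(out))))
}

#' Impute every strain of a panel
#'
#' Applies [impute_strain()] to each strain against all remaining strains
#' (imputation uses the original, not progressively imputed, calls, so
#' strain order does not matter). The summary reports the median and
#' maximum residual missing fraction across strains.
#'
#' @param gm A [genotype_matrix()].
#' @param params An [hmm_params()].
#' @return List with `genotypes` (imputed [genotype_matrix()]) and
#'   `summary` (per-strain pre/post missingness plus median/max residual).
#' @export
impute_panel <- function(gm, params = hmm_params()) {
  calls <- gm$calls
  pre <- post <- numeric(length(gm$strains))
  for (j in seq_along(gm$strains)) {
    res <- impute_strain(gm, gm$strains[j], params)
    calls[, j] <- res$calls
    pre[j] <- res$report$pre_missing
    post[j] <- res$report$post_missing
  }
  out <- genotype_matrix(gm$variants, gm$strains, calls)
  summary <- list(
    per_strain = data.frame(strain = gm$strains, pre_missing = pre,
                            post_missing = post,
                            stringsAsFactors = FALSE),
    median_residual_missing = stats::median(post),
    max_residual_missing = max(post))
  list(genotypes = out, summary = summary)
}
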