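# Guilt-by-association functional prioritization. Trait-related gene sets
# are clustered into modules (< 400 genes) on their network connectivity
# profiles; each module trains an ensemble of linear-kernel SVMs that
# separate module genes from balanced random negatives, using each gene's
# connectivity weights to the module genes as features. Candidate genes
# are scored by the ensembles and scores converted to empirical false
# positive rates against the out-of-fold negative score distribution.

# Feature matrix: each row is a gene's connectivity weights to the module
# genes. A gene's self-connectivity is undefined (the network has a zero
# diagonal), so for module genes the self entry is imputed with the
# gene's mean connectivity to the rest of the module; otherwise module
# genes would each carry one artificially zeroed feature.
feature_matrix <- function(net, genes, module_genes) {
  X <- net$weights[genes, module_genes, drop = FALSE]
  for (g in intersect(genes, module_genes)) {
    i <- match(g, genes)
    j <- match(g, module_genes)
    if (length(module_genes) > 1L) X[i, j] <- mean(X[i, -j])
  }
  X
}

#' Cluster a trait gene set into network modules under a size bound
#'
#' Average-linkage hierarchical clustering on correlation distance
#' between the set genes' network connectivity profiles. The tree is cut
#' at the shallowest level at which every cluster is smaller than
#' `max_size`; clusters smaller than `min_size` are then merged into
#' their nearest sibling (smallest average inter-cluster distance).
#'
#' @param genes Character vector: the trait gene set.
#' @param net A [functional_network()].
#' @param max_size Strict upper bound on module size.
#' @param min_size Clusters below this size are merged.
#' @return List of modules, each a list with `parent` (attribute set via
#'   names upstream), `genes`, and `parent_genes` (the full set as found
#'   in the network).
#' @export
cluster_gene_set <- function(genes, net, max_size = 400, min_size = 5) {
  stopifnot(inherits(net, "functional_network"))
  present <- intersect(genes, net$gene_ids)
  if (length(present) == 0L)
    stop("gene set entirely absent from network: ",
         paste(utils::head(genes, 10), collapse = ", "))
  make <- function(members) list(genes = members, parent_genes = present)
  if (length(present) < max_size) return(list(make(present)))
  prof <- net$weights[present, , drop = FALSE]
  cc <- suppressWarnings(stats::cor(t(prof)))
  cc[is.na(cc)] <- 0
  d <- stats::as.dist(1 - cc)
  hc <- stats::hclust(d, method = "average")
  assign <- NULL
  for (k in seq_along(present)) {
    ct <- stats::cutree(hc, k = k)
    if (max(table(ct)) < max_size) { assign <- ct; break }
  }
  if (is.null(assign))
    stop("cannot partition the set into clusters smaller than ", max_size)
  dm <- as.matrix(d)
  repeat {
    sizes <- table(assign)
    small <- names(sizes)[sizes < min_size]
    if (length(small) == 0L || length(sizes) == 1L) break
    cl <- small[1L]
    others <- setdiff(names(sizes), cl)
    avg <- vapply(others, function(o)
      mean(dm[assign == cl, assign == o, drop = FALSE]), 0)
    assign[assign == cl] <- others[which.min(avg)]
  }
  lapply(unique(assign), function(cl) make(present[assign == cl]))
}

# Out-of-fold decision scores for one SVM over a labelled gene sample.
# Returns scores oriented so that higher = more module-like, plus the
# model refit on all rows (same orientation) for scoring new genes.
svm_cv_scores <- function(X, y, cost, folds) {
  n <- nrow(X)
  # stratified folds: unbalanced training folds shift the decision
  # offset and bias pooled out-of-fold scores
  fold <- integer(n)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  oof <- numeric(n)
  for (f in seq_len(folds)) {
    te <- fold == f
    if (all(te) || !any(te)) next
    fit <- e1071::svm(X[!te, , drop = FALSE],
                      factor(y[!te], levels = c(0, 1)),
                      kernel = "linear", cost = cost, scale = FALSE)
    dv <- attr(stats::predict(fit, X[te, , drop = FALSE],
                              decision.values = TRUE),
               "decision.values")[, 1L]
    # orient within the training fold: positives should score higher
    tr_dv <- attr(stats::predict(fit, X[!te, , drop = FALSE],
                                 decision.values = TRUE),
                  "decision.values")[, 1L]
    flip <- mean(tr_dv[y[!te] == 1]) < mean(tr_dv[y[!te] == 0])
    oof[te] <- if (flip) -dv else dv
  }
  full <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                     cost = cost, scale = FALSE)
  dv_full <- attr(stats::predict(full, X, decision.values = TRUE),
                  "decision.values")[, 1L]
  flip_full <- mean(dv_full[y == 1]) < mean(dv_full[y == 0])
  list(oof = oof, model = full, flip = flip_full)
}

#' Tune the SVM cost series by iterative window narrowing
#'
#' Evaluates 10-fold cross-validated accuracy at eight log-spaced cost
#' values, re-centers a half-width window on the best cost, and repeats
#' for `rounds` rounds; the final eight values are the cost series used
#' by the ensemble.
#'
#' @param module A module from [cluster_gene_set()].
#' @param net A [functional_network()].
#' @param seed Integer seed (negative sampling and fold assignment).
#' @param rounds Number of narrowing rounds.
#' @param folds CV folds.
#' @param window Initial cost window (positive, log-spaced search).
#' @return Numeric vector of eight positive cost values.
#' @export
tune_cost <- function(module, net, seed, rounds = 3, folds = 10,
                      window = c(1e-3, 1e3)) {
  stopifnot(inherits(net, "functional_network"))
  pos <- module$genes
  pool <- setdiff(net$gene_ids, module$parent_genes)
  if (length(pool) < length(pos))
    stop("network too small for a balanced negative sample")
  withr::with_seed(seed, {
    neg <- sample(pool, length(pos))
    X <- rbind(feature_matrix(net, pos, pos),
               feature_matrix(net, neg, pos))
    y <- rep(c(1, 0), c(length(pos), length(neg)))
    lw <- log10(window)
    costs <- NULL
    for (r in seq_len(rounds)) {
      costs <- 10^seq(lw[1L], lw[2L], length.out = 8L)
      acc <- vapply(costs, function(cst) {
        sc <- svm_cv_scores(X, y, cst, folds)
        mean((sc$oof > 0) == (y == 1))
      }, 0)
      best <- log10(costs[which.max(acc)])
      half <- (lw[2L] - lw[1L]) / 4   # half of the halved width
      lw <- c(best - half, best + half)
    }
    costs
  })
}

#' Train an SVM ensemble for one functional module
#'
#' Each of `n_svms` classifiers draws an independent balanced negative
#' sample (module-sized, from genes outside the parent set), is trained
#' with a linear kernel at a cost cycled from the tuned series, and
#' contributes its out-of-fold decision scores: negatives to the null
#' distribution used for FPR conversion, positives for held-out
#' performance assessment.
#'
#' @param module A module from [cluster_gene_set()].
#' @param net A [functional_network()].
#' @param costs Cost series (typically from [tune_cost()]).
#' @param seed Integer seed.
#' @param n_svms Ensemble size.
#' @param folds CV folds.
#' @param name Module name carried into score tables.
#' @return Object of class `module_classifier_ensemble`.
#' @export
train_ensemble <- function(module, net, costs, seed, n_svms = 100,
                           folds = 10, name = "module") {
  stopifnot(inherits(net, "functional_network"))
  pos <- module$genes
  pool <- setdiff(net$gene_ids, module$parent_genes)
  if (length(pool) < length(pos))
    stop("network must contain at least 2x the module size")
  withr::with_seed(seed, {
    models <- vector("list", n_svms)
    flips <- logical(n_svms)
    null_scores <- numeric(0)
    pos_oof <- numeric(0)
    neg_genes <- vector("list", n_svms)
    for (i in seq_len(n_svms)) {
      neg <- sample(pool, length(pos))
      neg_genes[[i]] <- neg
      X <- rbind(feature_matrix(net, pos, pos),
                 feature_matrix(net, neg, pos))
      y <- rep(c(1, 0), c(length(pos), length(neg)))
      sc <- svm_cv_scores(X, y, costs[(i - 1L) %% length(costs) + 1L],
                          folds)
      models[[i]] <- sc$model
      flips[i] <- sc$flip
      null_scores <- c(null_scores, sc$oof[y == 0])
      pos_oof <- c(pos_oof, sc$oof[y == 1])
    }
    structure(list(name = name, module_genes = pos,
                   parent_genes = module$parent_genes, models = models,
                   flips = flips, null_scores = null_scores,
                   pos_oof = pos_oof, costs = costs, net = net,
                   n_svms = n_svms),
              class = "module_classifier_ensemble")
  })
}

#' Held-out AUROC of an ensemble
#'
#' Computed from the stored out-of-fold decision scores of module genes
#' versus sampled negatives.
#'
#' @param ens A [train_ensemble()] result.
#' @return AUROC in [0, 1].
#' @export
ensemble_auroc <- function(ens) {
  stopifnot(inherits(ens, "module_classifier_ensemble"))
  auroc(ens$pos_oof, ens$null_scores)
}

auroc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  np <- length(pos); nn <- length(neg)
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

# Mean oriented decision value of the ensemble for given genes (must be
# present in the ensemble's network).
ensemble_scores <- function(ens, genes) {
  if (length(genes) == 0L) return(numeric(0))
  X <- feature_matrix(ens$net, genes, ens$module_genes)
  s <- matrix(0, length(genes), ens$n_svms)
  for (i in seq_len(ens$n_svms)) {
    dv <- attr(stats::predict(ens$models[[i]], X,
                              decision.values = TRUE),
               "decision.values")[, 1L]
    s[, i] <- if (ens$flips[i]) -dv else dv
  }
  rowMeans(s)
}

#' Score positional candidate genes against module ensembles
#'
#' Per gene and module, the score is the mean decision value over the
#' ensemble's SVMs; the per-module FPR is the fraction of null scores at
#' or above it, floored at 1/(n_null + 1). Each gene's final FPR is the
#' minimum over all modules (its maximum functional enrichment), reported
#' with -log10(FPR). Candidates absent from the network get FPR 1 with a
#' warning.
#'
#' @param ensembles List of [train_ensemble()] results.
#' @param candidates Character vector of candidate gene ids.
#' @return data.frame with `gene_id`, `best_module`, `score`, `fpr`,
#'   `neglog10_fpr`.
#' @export
score_candidates <- function(ensembles, candidates) {
  if (inherits(ensembles, "module_classifier_ensemble"))
    ensembles <- list(ensembles)
  net_genes <- ensembles[[1L]]$net$gene_ids
  absent <- setdiff(candidates, net_genes)
  if (length(absent))
    warning("candidate(s) absent from network get FPR 1: ",
            paste(absent, collapse = ", "))
  present <- intersect(candidates, net_genes)
  per_mod <- lapply(ensembles, function(ens) {
    s <- ensemble_scores(ens, present)
    n_null <- length(ens$null_scores)
    fpr <- vapply(s, function(x) mean(ens$null_scores >= x), 0)
    fpr <- pmax(fpr, 1 / (n_null + 1))
    list(score = s, fpr = fpr)
  })
  fprs <- do.call(cbind, lapply(per_mod, `[[`, "fpr"))
  scores <- do.call(cbind, lapply(per_mod, `[[`, "score"))
  mod_names <- vapply(ensembles, `[[`, "", "name")
  if (length(present)) {
    best <- apply(fprs, 1L, which.min)
    res_present <- data.frame(
      gene_id = present, best_module = mod_names[best],
      score = scores[cbind(seq_along(present), best)],
      fpr = fprs[cbind(seq_along(present), best)],
      stringsAsFactors = FALSE)
  } else {
    res_present <- data.frame(gene_id = character(0),
                              best_module = character(0),
                              score = numeric(0), fpr = numeric(0),
                              stringsAsFactors = FALSE)
  }
  res <- rbind(res_present,
               if (length(absent))
                 data.frame(gene_id = absent, best_module = NA_character_,
                            score = NA_real_, fpr = 1,
                            stringsAsFactors = FALSE))
  res <- res[match(candidates, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res$neglog10_fpr <- -log10(res$fpr)
  res
}
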