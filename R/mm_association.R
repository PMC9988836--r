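# Efficient mixed-model association across inbred strains.
#
# Model: y = X beta + u + e with u ~ N(0, sigma_g2 * K) and
# e ~ N(0, sigma_e2 * I); delta = sigma_e2 / sigma_g2. Maximum-likelihood
# (not REML) fitting, matching the likelihood-ratio testing convention of
# EMMA's emma.ML.LRT: a single eigendecomposition of K turns every
# evaluation of the profile log-likelihood in delta into O(n) work, the
# profile is maximized over a log-spaced delta grid with bisection
# refinement of derivative sign changes, and each SNP is tested with
# 2 * (loglik_full - loglik_null) against chi-square(1).

#' Identity-by-state kinship matrix from a genotype panel
#'
#' K[i, j] is the proportion of SNPs, non-missing in both strains, at
#' which the two strains carry identical calls.
#'
#' @param gm A [genotype_matrix()].
#' @return List of class `kinship_matrix` with `strains` and the symmetric
#'   matrix `K` (unit diagonal, entries in [0, 1]).
#' @export
ibs_kinship <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (length(gm$strains) < 2L) stop("need >= 2 strains")
  M <- gm$calls
  A <- (M == 1L); A[is.na(A)] <- FALSE; storage.mode(A) <- "double"
  B <- (M == 0L); B[is.na(B)] <- FALSE; storage.mode(B) <- "double"
  obs <- !is.na(M); storage.mode(obs) <- "double"
  matches <- crossprod(A) + crossprod(B)
  overlap <- crossprod(obs)
  if (any(overlap == 0))
    stop("strain pair(s) share no jointly observed SNP")
  K <- matches / overlap
  structure(list(strains = gm$strains, K = K), class = "kinship_matrix")
}

# Eigendecomposition with PSD enforcement (ridge 1e-6 if needed).
kinship_eigen <- function(K) {
  ev <- eigen(K, symmetric = TRUE)
  if (min(ev$values) < 0) {
    ev$values <- ev$values + 1e-6
    if (min(ev$values) < 0)
      stop("kinship matrix is not positive semidefinite after ridge 1e-6")
  }
  ev
}

# Profile ML log-likelihood machinery on rotated data.
# ystar = U'y, Xstar = U'X, lambda = eigenvalues of K.
emma_eval <- function(logdelta, ystar, Xstar, lambda) {
  delta <- exp(logdelta)
  n <- length(ystar)
  sw <- sqrt(1 / (lambda + delta))
  Xw <- Xstar * sw
  yw <- ystar * sw
  fit <- stats::lm.fit(Xw, yw)
  rw <- fit$residuals
  Q <- sum(rw^2)
  w <- sw^2
  loglik <- -0.5 * (n * log(2 * pi) + n * log(Q / n) + n +
                      sum(log(lambda + delta)))
  # envelope-theorem derivative of the profile log-likelihood w.r.t.
  # log(delta)
  dldd <- 0.5 * (n * sum(rw^2 * w) / Q - sum(w)) * delta
  list(loglik = loglik, dloglik = dldd, beta = fit$coefficients,
       sigma_g2 = Q / n)
}

emma_profile <- function(ystar, Xstar, lambda,
                         delta_range = c(1e-5, 1e5), n_grid = 100L,
                         tol = 1e-6) {
  grid <- seq(log(delta_range[1]), log(delta_range[2]),
              length.out = n_grid)
  evals <- lapply(grid, emma_eval, ystar = ystar, Xstar = Xstar,
                  lambda = lambda)
  ll <- vapply(evals, `[[`, 0, "loglik")
  dl <- vapply(evals, `[[`, 0, "dloglik")
  cand <- c(grid[1L], grid[n_grid])
  sign_change <- which(dl[-n_grid] > 0 & dl[-1L] <= 0)
  for (i in sign_change) {
    lo <- grid[i]; hi <- grid[i + 1L]
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      d <- emma_eval(mid, ystar, Xstar, lambda)$dloglik
      if (d > 0) lo <- mid else hi <- mid
    }
    cand <- c(cand, (lo + hi) / 2)
  }
  cll <- vapply(cand, function(g)
    emma_eval(g, ystar, Xstar, lambda)$loglik, 0)
  best <- cand[which.max(cll)]
  out <- emma_eval(best, ystar, Xstar, lambda)
  out$delta <- exp(best)
  out$boundary <- best <= grid[1L] + tol || best >= grid[n_grid] - tol
  out
}

#' Fit the linear mixed model by maximum likelihood
#'
#' @param y Numeric phenotype vector (binary traits coded 0/1).
#' @param X Fixed-effect design matrix (full column rank), one row per
#'   strain; defaults to an intercept.
#' @param K Kinship: a [ibs_kinship()] result or a plain symmetric matrix.
#' @param delta_range,n_grid,tol Profile-search settings: log-spaced grid
#'   of `n_grid` points over `delta_range` for delta = sigma_e2/sigma_g2,
#'   with derivative sign changes refined by bisection to `tol` on
#'   log(delta).
#' @return List of class `mixed_model_fit`: `sigma_g2`, `sigma_e2`,
#'   `delta`, `beta`, `loglik`, and `boundary` (TRUE when the optimum sat
#'   at a grid edge).
#' @export
fit_mixed_model <- function(y, X = NULL, K, delta_range = c(1e-5, 1e5),
                            n_grid = 100L, tol = 1e-6) {
  if (inherits(K, "kinship_matrix")) K <- K$K
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  stopifnot(nrow(X) == n, nrow(K) == n, ncol(K) == n)
  if (qr(X)$rank < ncol(X)) stop("X must have full column rank")
  ev <- kinship_eigen(K)
  ystar <- drop(crossprod(ev$vectors, y))
  Xstar <- crossprod(ev$vectors, X)
  prof <- emma_profile(ystar, Xstar, ev$values, delta_range, n_grid, tol)
  structure(list(sigma_g2 = prof$sigma_g2,
                 sigma_e2 = prof$sigma_g2 * prof$delta,
                 delta = prof$delta, beta = prof$beta,
                 loglik = prof$loglik, boundary = prof$boundary),
            class = "mixed_model_fit")
}

#' Per-SNP likelihood-ratio mixed-model association scan
#'
#' For each SNP the full model (intercept + SNP) and the null model
#' (intercept only) are ML-fitted on the strains with an observed call at
#' that SNP, and LRT = 2 (loglik_full - loglik_null) is referred to the
#' chi-square(1) upper tail. Strains missing a SNP are dropped for that
#' SNP only; null fits and eigendecompositions are shared across SNPs
#' with the same missingness pattern. Monomorphic SNPs get p = 1 and are
#' flagged.
#'
#' @param gm A [genotype_matrix()].
#' @param phenotype Numeric vector aligned with `gm$strains` (or named by
#'   strain). Binary phenotypes are coded 0/1 and treated as quantitative.
#' @param K Kinship ([ibs_kinship()] result or matrix) over the same
#'   strains.
#' @param delta_range,n_grid,tol See [fit_mixed_model()].
#' @return data.frame with columns `snp_id`, `chrom`, `pos`,
#'   `n_strains_used`, `lrt_stat`, `p_value`, `monomorphic`.
#' @export
lrt_scan <- function(gm, phenotype, K, delta_range = c(1e-5, 1e5),
                     n_grid = 100L, tol = 1e-6) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (!is.null(names(phenotype)))
    phenotype <- phenotype[gm$strains]
  if (length(phenotype) != length(gm$strains))
    stop("phenotype must cover every strain")
  if (anyNA(phenotype)) stop("phenotype contains missing values")
  if (inherits(K, "kinship_matrix")) K <- K$K
  n_all <- length(gm$strains)
  stopifnot(nrow(K) == n_all)
  null_cache <- new.env(parent = emptyenv())
  get_null <- function(use) {
    key <- paste(which(use), collapse = ",")
    hit <- null_cache[[key]]
    if (!is.null(hit)) return(hit)
    ev <- kinship_eigen(K[use, use, drop = FALSE])
    ystar <- drop(crossprod(ev$vectors, phenotype[use]))
    ones <- crossprod(ev$vectors, matrix(1, sum(use), 1))
    l0 <- emma_profile(ystar, ones, ev$values, delta_range, n_grid,
                       tol)$loglik
    hit <- list(ev = ev, ystar = ystar, ones = ones, loglik0 = l0)
    null_cache[[key]] <- hit
    hit
  }
  rows <- lapply(seq_len(nrow(gm$calls)), function(i) {
    x <- gm$calls[i, ]
    use <- !is.na(x)
    v <- gm$variants[i, ]
    base <- data.frame(snp_id = v$snp_id, chrom = v$chrom, pos = v$pos,
                       n_strains_used = sum(use), lrt_stat = 0,
                       p_value = 1, monomorphic = FALSE,
                       stringsAsFactors = FALSE)
    if (sum(use) < 3L || length(unique(x[use])) < 2L) {
      base$monomorphic <- TRUE
      return(base)
    }
    nul <- get_null(use)
    Xs <- cbind(nul$ones,
                crossprod(nul$ev$vectors, as.numeric(x[use])))
    l1 <- emma_profile(nul$ystar, Xs, nul$ev$values, delta_range,
                       n_grid, tol)$loglik
    base$lrt_stat <- max(0, 2 * (l1 - nul$loglik0))
    base$p_value <- stats::pchisq(base$lrt_stat, df = 1,
                                  lower.tail = FALSE)
    base
  })
  do.call(rbind, rows)
}
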