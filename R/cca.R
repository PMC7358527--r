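#' Canonical correspondence analysis
#'
#' ter Braak's CCA: the species matrix is converted to chi-square-standardised
#' residuals Q = (P - r c') / sqrt(r c') (P the proportion matrix, r and c its
#' row and column mass vectors), Q is projected by weighted least squares onto
#' the environmental predictors (rows weighted by sqrt(r), predictors centred
#' to weighted mean zero), and the projection is eigen-decomposed by SVD.
#' Constrained eigenvalues are the squared singular values; the fraction of
#' variation per axis is the eigenvalue over the total inertia sum(Q^2).
#'
#' Site scores are reported in Hill's scaling with a focus on inter-sample
#' distances: the weighted-orthonormal site vectors u_k / sqrt(r) are divided
#' by sqrt(1 - lambda_k), so axes with stronger structure are stretched less
#' and inter-sample chi-square distances are approximated. Species scores are
#' the column-mass-standardised right singular vectors.
#'
#' Optional down-weighting of rare species multiplies the abundances of
#' species occurring in fewer than max(frequency)/5 samples by
#' frequency / (max(frequency)/5) before the analysis.
#'
#' @param species Non-negative samples x species (TRF-bin) matrix with
#'   positive row sums.
#' @param env Samples x predictors data frame or matrix (numeric, full column
#'   rank, fewer predictors than samples).
#' @param downweight_rare Apply the rare-species down-weighting rule.
#' @return A list of class `cca_fit`: `eigenvalues`, `pct_variation`,
#'   `total_inertia`, `site_scores` (Hill's scaling), `species_scores`,
#'   `rank`.
#' @export
cca <- function(species, env, downweight_rare = FALSE) {
  Y <- as.matrix(species)
  if (any(Y < 0)) stop("species matrix must be non-negative")
  if (any(rowSums(Y) <= 0)) stop("species matrix must have positive row sums")
  zero_col <- colSums(Y) <= 0
  if (any(zero_col)) {
    warning("dropping ", sum(zero_col), " empty species column(s)")
    Y <- Y[, !zero_col, drop = FALSE]
  }
  X <- as.matrix(as.data.frame(env))
  if (!is.numeric(X)) stop("predictors must be numeric")
  if (nrow(X) != nrow(Y)) stop("species and env must have matching rows")
  if (ncol(X) >= nrow(X)) stop("need more samples than predictors")
  if (downweight_rare) {
    f <- colSums(Y > 0)
    thr <- max(f) / 5
    w <- pmin(1, f / thr)
    Y <- sweep(Y, 2, w, `*`)
  }
  P <- Y / sum(Y)
  r <- rowSums(P)
  cm <- colSums(P)
  Q <- (P - r %o% cm) / sqrt(r %o% cm)
  total_inertia <- sum(Q^2)
  # weighted centring and row weighting of predictors
  wmean <- colSums(X * r)
  Xc <- sweep(X, 2, wmean)
  Xw <- Xc * sqrt(r)
  qrX <- qr(Xw)
  if (qrX$rank < ncol(Xw)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(Xw)]]
    stop("collinear predictor(s): ", paste(bad, collapse = ", "))
  }
  Qhat <- qr.fitted(qrX, Q)
  sv <- svd(Qhat)
  keep <- sv$d^2 > max(sv$d^2, 0) * 1e-12 & sv$d^2 > 1e-14
  lambda <- sv$d[keep]^2
  naxes <- length(lambda)
  if (naxes == 0) stop("no non-trivial constrained axes")
  U <- sv$u[, keep, drop = FALSE]
  V <- sv$v[, keep, drop = FALSE]
  sites <- U / sqrt(r)
  hill <- sweep(sites, 2, sqrt(pmax(1 - lambda, 1e-12)), `/`)
  spp <- V / sqrt(cm)
  dimnames(hill) <- list(rownames(Y), paste0("CCA", seq_len(naxes)))
  dimnames(spp) <- list(colnames(Y), paste0("CCA", seq_len(naxes)))
  structure(list(
    eigenvalues = lambda,
    pct_variation = 100 * lambda / total_inertia,
    total_inertia = total_inertia,
    site_scores = hill,
    species_scores = spp,
    rank = naxes
  ), class = "cca_fit")
}

# sum of constrained eigenvalues (trace) without the SVD; used by the
# permutation test
cca_trace <- function(Q, X, r) {
  wmean <- colSums(X * r)
  Xw <- sweep(X, 2, wmean) * sqrt(r)
  sum(qr.fitted(qr(Xw), Q)^2)
}

#' Monte Carlo permutation test for CCA
#'
#' Permutes the sample rows of the environmental matrix and recomputes the
#' sum of constrained eigenvalues (the trace). The p-value uses the add-one
#' convention p = (1 + #\{perm trace >= observed\}) / (1 + n_perm), so it is
#' never exactly zero.
#'
#' @inheritParams cca
#' @param n_perm Number of permutations (>= 99).
#' @param seed Seed for the permutation stream.
#' @return A list of class `cca_permutation`: `p`, `observed_trace`,
#'   `n_perm`, `perm_traces`.
#' @export
cca_permutation_test <- function(species, env, n_perm = 999, seed = NULL,
                                 downweight_rare = FALSE) {
  if (n_perm < 99) stop("n_perm must be >= 99")
  Y <- as.matrix(species)
  if (downweight_rare) {
    f <- colSums(Y > 0)
    thr <- max(f) / 5
    Y <- sweep(Y, 2, pmin(1, f / thr), `*`)
  }
  X <- as.matrix(as.data.frame(env))
  P <- Y / sum(Y)
  r <- rowSums(P)
  cm <- colSums(P)
  Q <- (P - r %o% cm) / sqrt(r %o% cm)
  obs <- cca_trace(Q, X, r)
  n <- nrow(X)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      cca_trace(Q, X[sample.int(n), , drop = FALSE], r)
    }, numeric(1))
  })
  p <- (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm)
  structure(list(p = p, observed_trace = obs, n_perm = n_perm,
                 perm_traces = perm), class = "cca_permutation")
}
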