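#' Nonmetric multidimensional scaling (Kruskal stress-1)
#'
#' Kruskal's iterative scheme: the configuration is initialised from
#' classical (metric) scaling of the dissimilarities, then alternates
#' (a) monotone regression of the configuration distances onto the rank order
#' of the dissimilarities (pool-adjacent-violators, primary treatment of
#' ties) and (b) a steepest-descent step on stress-1,
#' sqrt(sum((d - dhat)^2) / sum(d^2)), with step-halving so the recorded
#' stress sequence never increases. Seeded random restarts guard against
#' local minima; the lowest-stress solution is returned.
#'
#' Exact-zero off-diagonal dissimilarities (identical profiles) break the
#' rank-based fit; they are replaced by half the smallest positive
#' dissimilarity with a warning.
#'
#' @param D Symmetric dissimilarity matrix (zero diagonal).
#' @param k Target dimensionality (default 2); requires `nrow(D) > k`.
#' @param max_iter Maximum descent iterations per start.
#' @param tol Convergence tolerance on the stress decrease.
#' @param seed Seed controlling the random restarts.
#' @param n_restarts Number of random starts in addition to the classical
#'   initialisation (default 4).
#' @return A list of class `nmds` with `points` (n x k, labelled), `stress`,
#'   `stress_trace` (of the winning start), and `converged`.
#' @export
nmds <- function(D, k = 2, max_iter = 300, tol = 1e-6, seed = NULL,
                 n_restarts = 4) {
  D <- unclass(as.matrix(D))
  n <- nrow(D)
  if (n <= k) stop("need more points than dimensions")
  labs <- rownames(D) %||% paste0("P", seq_len(n))
  lo <- D[lower.tri(D)]
  if (any(lo == 0)) {
    pos <- lo[lo > 0]
    if (length(pos) == 0) stop("all dissimilarities are zero")
    repl <- min(pos) / 2
    warning("zero off-diagonal dissimilarities replaced by ", repl)
    D[D == 0] <- repl
    diag(D) <- 0
  }
  delta <- D[lower.tri(D)]

  with_seed(seed, {
    starts <- list(nmds_classical_start(D, k))
    scale0 <- sqrt(mean(delta^2))
    for (r in seq_len(n_restarts)) {
      starts[[r + 1]] <- matrix(stats::rnorm(n * k, sd = scale0 / 2), n, k)
    }
    best <- NULL
    for (X0 in starts) {
      fit <- nmds_one_start(X0, delta, n, k, max_iter, tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    rownames(best$points) <- labs
    structure(best, class = "nmds")
  })
}

# classical (Torgerson) scaling start, padded if D yields < k positive axes
nmds_classical_start <- function(D, k) {
  cs <- stats::cmdscale(D, k = k)
  n <- nrow(D)
  if (ncol(cs) < k) {
    pad <- matrix(stats::rnorm(n * (k - ncol(cs)), sd = 1e-4), n)
    cs <- cbind(cs, pad)
  }
  cs
}

# distances of configuration rows, lower-triangle order matching lower.tri
config_dist <- function(X) {
  as.numeric(stats::dist(X))
}

# monotone (isotonic) disparities: primary treatment of ties — within blocks
# of tied dissimilarities, distances are pre-sorted ascending so they impose
# no constraint on each other
nmds_disparities <- function(delta, d) {
  ord <- order(delta, d)
  fit <- stats::isoreg(seq_along(ord), d[ord])$yf
  dhat <- numeric(length(d))
  dhat[ord] <- fit
  dhat
}

nmds_stress <- function(d, dhat) {
  sqrt(sum((d - dhat)^2) / sum(d^2))
}

nmds_one_start <- function(X, delta, n, k, max_iter, tol) {
  m <- length(delta)
  ij <- which(lower.tri(matrix(0, n, n)), arr.ind = TRUE)
  d <- pmax(config_dist(X), 1e-12)
  dhat <- nmds_disparities(delta, d)
  stress <- nmds_stress(d, dhat)
  trace <- stress
  step <- 0.2
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # gradient of stress-1 w.r.t. X at fixed disparities
    S <- sum((d - dhat)^2)
    T <- sum(d^2)
    if (T == 0 || stress == 0) { converged <- TRUE; break }
    gd <- ((d - dhat) * T - S * d) / (stress * T^2)  # d stress / d d_ij
    G <- matrix(0, n, k)
    diff <- X[ij[, 1], , drop = FALSE] - X[ij[, 2], , drop = FALSE]
    coef <- gd / d
    for (dim_i in seq_len(k)) {
      v <- coef * diff[, dim_i]
      G[, dim_i] <- tapply(c(v, -v), c(ij[, 1], ij[, 2]), sum)[as.character(seq_len(n))]
    }
    G[is.na(G)] <- 0
    gn <- sqrt(sum(G^2))
    if (gn < 1e-14) { converged <- TRUE; break }
    scaleX <- sqrt(sum(X^2) / n) + 1e-12
    improved <- FALSE
    s <- step
    for (h in seq_len(30)) {
      Xn <- X - s * scaleX * G / gn
      dn <- pmax(config_dist(Xn), 1e-12)
      dhn <- nmds_disparities(delta, dn)
      sn <- nmds_stress(dn, dhn)
      if (sn <= stress) {
        improved <- TRUE
        break
      }
      s <- s / 2
    }
    if (!improved) { converged <- TRUE; break }
    delta_stress <- stress - sn
    X <- Xn; d <- dn; dhat <- dhn; stress <- sn
    trace <- c(trace, stress)
    step <- min(0.5, s * 1.5)
    if (delta_stress < tol) { converged <- TRUE; break }
  }
  X <- sweep(X, 2, colMeans(X))
  list(points = X, stress = stress, stress_trace = trace,
       converged = converged)
}
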