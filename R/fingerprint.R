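#' Call bands from a densitometric lane trace
#'
#' Local intensity maxima at or above `min_profiling` of the maximum trace
#' intensity are called as bands; maxima between `grey_zone` and
#' `min_profiling` are returned separately as uncertain (for manual review)
#' and excluded from the band set by default; weaker maxima are dropped.
#'
#' @param trace A `data.frame` with columns `position` (bp) and `intensity`
#'   (>= 0), sorted by position.
#' @param min_profiling Minimum relative intensity for a confident band.
#' @param grey_zone Lower bound of the uncertain zone.
#' @return A list of class `band_profile` with numeric `bands` and
#'   `uncertain` (positions in bp).
#' @export
call_bands <- function(trace, min_profiling = 0.05, grey_zone = 0.02) {
  if (any(trace$intensity < 0)) stop("intensities must be >= 0")
  y <- trace$intensity
  mx <- max(y)
  if (mx == 0) {
    warning("flat trace: no bands called")
    return(structure(list(bands = numeric(0), uncertain = numeric(0)),
                     class = "band_profile"))
  }
  n <- length(y)
  is_max <- logical(n)
  for (i in seq_len(n)) {
    left <- if (i > 1) y[i - 1] else -Inf
    right <- if (i < n) y[i + 1] else -Inf
    is_max[i] <- y[i] > left && y[i] >= right && y[i] > 0
  }
  rel <- y / mx
  structure(list(
    bands = trace$position[is_max & rel >= min_profiling],
    uncertain = trace$position[is_max & rel >= grey_zone & rel < min_profiling]
  ), class = "band_profile")
}

#' Match band positions across fingerprint profiles
#'
#' Greedy left-to-right clustering of the pooled band positions: a band joins
#' the current column while it lies within the matching tolerance of the
#' column's running mean position. The tolerance is proportional to fragment
#' size by default (`tol_frac * running mean`), since gel mobility error grows
#' with size; pass `absolute_tol` for a fixed-bp tolerance instead.
#'
#' @param profiles Named list of numeric band-position vectors (bp), one per
#'   labelled lane.
#' @param tol_frac Proportional matching tolerance (default 0.02 = 2%).
#' @param absolute_tol Optional fixed tolerance in bp, overriding `tol_frac`.
#' @return Binary presence/absence matrix, profiles x consensus positions.
#' @export
match_bands <- function(profiles, tol_frac = 0.02, absolute_tol = NULL) {
  if (is.null(absolute_tol) && tol_frac <= 0) stop("tol_frac must be > 0")
  labs <- names(profiles)
  pooled <- data.frame(
    label = rep(labs, lengths(profiles)),
    position = unlist(profiles, use.names = FALSE)
  )
  pooled <- pooled[order(pooled$position), , drop = FALSE]
  n <- nrow(pooled)
  col <- integer(n)
  if (n > 0) {
    cidx <- 1L
    col[1] <- 1L
    msum <- pooled$position[1]
    cnt <- 1L
    for (i in seq_len(n)[-1]) {
      mu <- msum / cnt
      tol <- if (is.null(absolute_tol)) tol_frac * mu else absolute_tol
      if (abs(pooled$position[i] - mu) <= tol) {
        col[i] <- cidx
        msum <- msum + pooled$position[i]
        cnt <- cnt + 1L
      } else {
        cidx <- cidx + 1L
        col[i] <- cidx
        msum <- pooled$position[i]
        cnt <- 1L
      }
    }
  }
  cols <- vapply(split(pooled$position, col), mean, numeric(1))
  mat <- matrix(0L, nrow = length(labs), ncol = length(cols),
                dimnames = list(labs, sprintf("%.1f", cols)))
  for (i in seq_len(n)) mat[pooled$label[i], col[i]] <- 1L
  mat
}

#' Dice similarity between two binary band profiles
#'
#' 100 * 2|a AND b| / (|a| + |b|), where |.| counts present bands.
#'
#' @param a,b Binary (0/1 or logical) vectors over a shared band-column space.
#' @return Similarity percentage in \[0, 100\].
#' @export
dice_similarity <- function(a, b) {
  a <- as.logical(a)
  b <- as.logical(b)
  if (length(a) != length(b)) stop("profiles must share band-column space")
  na <- sum(a)
  nb <- sum(b)
  if (na + nb == 0) stop("undefined similarity: both profiles empty")
  100 * 2 * sum(a & b) / (na + nb)
}

#' Pairwise Dice similarity matrix
#'
#' @param presence Binary presence/absence matrix (profiles x band columns),
#'   e.g. from [match_bands()].
#' @return Symmetric matrix of class `similarity_matrix`, diagonal 100.
#' @export
similarity_matrix <- function(presence) {
  n <- nrow(presence)
  if (n < 2) stop("need >= 2 profiles")
  S <- matrix(100, n, n, dimnames = list(rownames(presence),
                                         rownames(presence)))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      S[i, j] <- S[j, i] <- dice_similarity(presence[i, ], presence[j, ])
    }
  }
  class(S) <- c("similarity_matrix", class(S))
  S
}

#' Transform a similarity matrix to dissimilarities
#'
#' Elementwise y_ij = 100 - x_ij; an involution (applying it twice recovers
#' the original matrix). The result is symmetric with zero diagonal.
#'
#' @param S A similarity matrix (percent scale).
#' @return A dissimilarity matrix of class `dissimilarity_matrix`.
#' @export
to_dissimilarity <- function(S) {
  D <- 100 - unclass(S)
  class(D) <- c("dissimilarity_matrix", "matrix", "array")
  D
}

#' Average (and maximum) off-diagonal dissimilarity
#'
#' Mean of the n(n-1)/2 strictly-upper-triangle entries, with the most
#' dissimilar pair reported alongside.
#'
#' @param D A symmetric dissimilarity matrix, n >= 2.
#' @return List with `mean`, `max`, and `max_pair` (labels of the most
#'   dissimilar pair).
#' @export
average_dissimilarity <- function(D) {
  D <- unclass(D)
  n <- nrow(D)
  if (is.null(n) || n < 2) stop("need an n >= 2 dissimilarity matrix")
  ut <- upper.tri(D)
  idx <- which(ut & D == max(D[ut]), arr.ind = TRUE)[1, ]
  list(mean = mean(D[ut]), max = max(D[ut]),
       max_pair = c(rownames(D)[idx[1]], colnames(D)[idx[2]]))
}

#' UPGMA clustering of a dissimilarity matrix
#'
#' Classic average-linkage agglomeration: merge the closest pair; the distance
#' between clusters is the unweighted arithmetic mean of all member pairwise
#' dissimilarities. Merge heights equal the merging distance itself (the
#' cophenetic convention), so [stats::cophenetic()] on the result returns the
#' average-linkage merge distances. Labels are sorted lexicographically before
#' clustering so distance ties break by label order.
#'
#' @param D A symmetric dissimilarity matrix with zero diagonal and labels.
#' @return An `hclust` object (ultrametric; also of class `upgma`).
#' @export
upgma <- function(D) {
  D <- unclass(D)
  labs <- rownames(D)
  if (is.null(labs)) labs <- rownames(D) <- colnames(D) <- paste0("L", seq_len(nrow(D)))
  o <- order(labs)
  D <- D[o, o, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  class(hc) <- c("upgma", "hclust")
  hc
}

#' Full fingerprint analysis pipeline
#'
#' From labelled band profiles to: binary presence matrix, Dice similarity
#' and dissimilarity matrices, average/maximum dissimilarity, UPGMA
#' dendrogram, and a 2-D nonmetric MDS ordination. When all profiles are
#' identical the dissimilarity matrix is degenerate and the MDS stage is
#' skipped with a warning.
#'
#' @param bands Either a named list of band-position vectors or a bands study
#'   table (columns `label`, `position`).
#' @param tol_frac Band-matching tolerance (see [match_bands()]).
#' @param seed Seed for the MDS random restarts.
#' @param mds_dim Ordination dimensionality.
#' @return A list of class `fingerprint_result`: `presence`, `similarity`,
#'   `dissimilarity`, `avg_dissimilarity`, `tree`, `mds`.
#' @export
fingerprint_pipeline <- function(bands, tol_frac = 0.02, seed = NULL,
                                 mds_dim = 2) {
  if (is.data.frame(bands)) {
    bands <- split(bands$position, as.character(bands$label))
  }
  if (length(bands) < 3) stop("need >= 3 labelled profiles")
  pres <- match_bands(bands, tol_frac = tol_frac)
  S <- similarity_matrix(pres)
  D <- to_dissimilarity(S)
  avg <- average_dissimilarity(D)
  tree <- upgma(D)
  mds <- if (max(unclass(D)[upper.tri(unclass(D))]) == 0) {
    warning("degenerate dissimilarity matrix (all profiles identical); ",
            "MDS skipped")
    NULL
  } else {
    nmds(D, k = mds_dim, seed = seed)
  }
  structure(list(presence = pres, similarity = S, dissimilarity = D,
                 avg_dissimilarity = avg, tree = tree, mds = mds),
            class = "fingerprint_result")
}
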