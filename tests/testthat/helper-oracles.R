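# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: set arithmetic for Dice, exhaustive recomputation
# from the original matrix for average linkage, and the classical rank
# formula for Spearman.

# Dice similarity via explicit set operations on band index sets
dice_oracle <- function(a, b) {
  A <- which(as.logical(a))
  B <- which(as.logical(b))
  100 * 2 * length(intersect(A, B)) / (length(A) + length(B))
}

# Exhaustive average-linkage (UPGMA) clustering: at every step scan all
# cluster pairs, computing their distance as the mean of the original
# pairwise dissimilarities, merge the closest pair, and record the merge
# distance as the cophenetic height of every cross-pair.
upgma_cophenetic_oracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = dimnames(D))
  while (length(clusters) > 1) {
    bd <- Inf
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bd - 1e-15) {
          bd <- d
          best <- c(i, j)
        }
      }
    }
    ci <- clusters[[best[1]]]
    cj <- clusters[[best[2]]]
    coph[ci, cj] <- bd
    coph[cj, ci] <- bd
    clusters[[best[1]]] <- c(ci, cj)
    clusters[[best[2]]] <- NULL
  }
  coph
}

# Classical Spearman rank formula 1 - 6*sum(d^2)/(n(n^2-1)); exact for
# tie-free data
spearman_formula_oracle <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Random symmetric dissimilarity matrix with zero diagonal
random_dissimilarity <- function(n, lo = 10, hi = 100) {
  D <- matrix(0, n, n)
  D[upper.tri(D)] <- stats::runif(n * (n - 1) / 2, lo, hi)
  D <- D + t(D)
  dimnames(D) <- list(LETTERS[seq_len(n)], LETTERS[seq_len(n)])
  D
}

# One-way repeated-measures F from explicit sums of squares
rm_anova_ss_oracle <- function(values, groups, subjects) {
  groups <- factor(groups)
  subjects <- factor(subjects)
  gm <- mean(values)
  k <- nlevels(groups)
  s <- nlevels(subjects)
  mg <- tapply(values, groups, mean)
  ms <- tapply(values, subjects, mean)
  ss_group <- s * sum((mg - gm)^2)
  ss_subj <- k * sum((ms - gm)^2)
  ss_tot <- sum((values - gm)^2)
  ss_err <- ss_tot - ss_group - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (s - 1)
  (ss_group / df1) / (ss_err / df2)
}

# Hand-built 3-replicate, 2-sample T-RFLP fixture: sample s1 carries one
# irreproducible peak (300 nt, replicate 3 only) and one reproducible peak at
# 0.05% of total fluorescence (250 nt); each consensus peak of s1 pairs with
# one of s2 under 0.5-nt binning.
trflp_fixture <- function() {
  s1 <- rbind(
    data.frame(replicate = 1,
               size = c(100.0, 150.0, 200.0, 250.0),
               height = c(1000, 500, 499, 1)),
    data.frame(replicate = 2,
               size = c(100.1, 150.1, 200.1, 250.1),
               height = c(991, 508, 500, 1)),
    data.frame(replicate = 3,
               size = c(99.9, 149.9, 200.2, 249.9, 300.0),
               height = c(1009, 492, 498, 1, 50))
  )
  s2 <- data.frame(replicate = rep(1:3, each = 3),
                   size = rep(c(100.3, 150.4, 200.5), 3),
                   height = rep(c(600, 300, 100), 3))
  rbind(cbind(sample_id = "s1", s1), cbind(sample_id = "s2", s2))
}

# a small balanced study for statistics tests
tiny_band_table <- function(seed = 1, turnover = 0.05) {
  generate_band_profiles(c("T1", "T4", "T7", "T8", "SF2"), study_months(),
                         turnover = turnover, seed = seed)
}
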