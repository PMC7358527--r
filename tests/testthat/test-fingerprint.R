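test_that("band calling separates confident, uncertain, and dropped maxima", {
  x <- seq(100, 700, by = 1)
  gauss <- function(mu, a) a * exp(-(x - mu)^2 / (2 * 4^2))
  tr <- data.frame(position = x,
                   intensity = gauss(400, 1.0) + gauss(250, 0.04) +
                     gauss(550, 0.01))
  bp <- call_bands(tr, min_profiling = 0.05, grey_zone = 0.02)
  expect_equal(bp$bands, 400)
  expect_equal(bp$uncertain, 250)

  single <- data.frame(position = x, intensity = gauss(400, 1))
  expect_equal(call_bands(single)$bands, 400)

  expect_warning(flat <- call_bands(data.frame(position = x, intensity = 0)),
                 "flat")
  expect_length(flat$bands, 0)
  expect_error(call_bands(data.frame(position = 1, intensity = -1)), ">= 0")
})

test_that("band matching uses a size-proportional tolerance", {
  pro <- list(l1 = c(400), l2 = c(406))
  m <- match_bands(pro, tol_frac = 0.02) # 2% of 400 is 8 bp
  expect_equal(ncol(m), 1)
  pro2 <- list(l1 = c(400), l2 = c(450))
  expect_equal(ncol(match_bands(pro2, tol_frac = 0.02)), 2)
  # identical profiles give identical rows
  pro3 <- list(a = c(200, 300, 400), b = c(200, 300, 400))
  m3 <- match_bands(pro3)
  expect_equal(unname(m3["a", ]), unname(m3["b", ]))
  # absolute-tolerance mode
  m4 <- match_bands(list(a = 100, b = 103), absolute_tol = 5)
  expect_equal(ncol(m4), 1)
})

test_that("Dice similarity agrees with the set-arithmetic oracle", {
  a <- c(1, 1, 1, 0) # bands 200,400,600
  b <- c(0, 1, 1, 1) # bands 400,600,800
  expect_equal(dice_similarity(a, b), 100 * 2 * 2 / (3 + 3))
  expect_equal(dice_similarity(a, a), 100)
  expect_equal(dice_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_error(dice_similarity(c(0, 0), c(0, 0)), "empty")

  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    x <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, 0.5)
    if (sum(x) + sum(y) == 0) next
    expect_identical(dice_similarity(x, y), dice_oracle(x, y))
  }
})

test_that("similarity and dissimilarity matrices obey their contracts", {
  pres <- rbind(a = c(1, 1, 0), b = c(1, 0, 1), c = c(0, 1, 1))
  S <- similarity_matrix(pres)
  expect_equal(dim(S), c(3, 3))
  expect_equal(unname(diag(unclass(S))), rep(100, 3))
  expect_true(isSymmetric(unclass(S)))
  D <- to_dissimilarity(S)
  expect_equal(unname(diag(unclass(D))), rep(0, 3))
  # involution
  expect_equal(unclass(to_dissimilarity(unclass(D))), unclass(S),
               ignore_attr = TRUE)
  # identical profiles: similarity 100 everywhere, dissimilarity 0
  pres2 <- rbind(a = c(1, 1), b = c(1, 1), c = c(1, 1))
  expect_true(all(unclass(similarity_matrix(pres2)) == 100))
  # linearity: mean dissimilarity = 100 - mean similarity
  ad <- average_dissimilarity(D)
  ut <- upper.tri(unclass(S))
  expect_equal(ad$mean, 100 - mean(unclass(S)[ut]))
})

test_that("average dissimilarity summarises the upper triangle", {
  D <- matrix(c(0, 10, 20, 10, 0, 30, 20, 30, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  ad <- average_dissimilarity(D)
  expect_equal(ad$mean, 20)
  expect_equal(ad$max, 30)
  expect_setequal(ad$max_pair, c("b", "c"))
  Z <- matrix(0, 3, 3)
  expect_equal(average_dissimilarity(Z)$mean, 0)
  C <- matrix(7, 3, 3); diag(C) <- 0
  expect_equal(average_dissimilarity(C)$mean, 7)
  expect_error(average_dissimilarity(matrix(0, 1, 1)), "n >= 2")
})

test_that("UPGMA reproduces hand traces and the brute-force oracle", {
  D <- matrix(c(0, 2, 8, 2, 0, 6, 8, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma(D)
  expect_equal(hc$height, c(2, 7)) # (A,B) at 2; ((A,B),C) at (8+6)/2

  # all-equal distances: every merge at the same height
  E <- matrix(5, 4, 4); diag(E) <- 0
  dimnames(E) <- list(letters[1:4], letters[1:4])
  expect_true(all(upgma(E)$height == 5))

  set.seed(13)
  for (i in 1:50) {
    R <- random_dissimilarity(6)
    hc <- upgma(R)
    co <- as.matrix(stats::cophenetic(hc))[LETTERS[1:6], LETTERS[1:6]]
    expect_equal(co, upgma_cophenetic_oracle(R), tolerance = 1e-9)
    # ultrametric: merge heights non-decreasing
    expect_true(all(diff(hc$height) >= -1e-12))
  }
})

test_that("nmds embeds exact configurations at zero stress", {
  X <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("p", 1:4), paste0("p", 1:4))
  f <- nmds(D, seed = 1)
  expect_lt(f$stress, 1e-6)
  # n = 3 in 2 dimensions is always embeddable
  D3 <- random_dissimilarity(3)
  expect_lt(nmds(D3, seed = 1)$stress, 1e-6)
})

test_that("nmds stress decreases monotonically and is seed-reproducible", {
  # near-embeddable geometry: 12 points in the plane with mild distortion
  set.seed(19)
  X <- matrix(runif(24, 0, 10), 12, 2)
  D <- as.matrix(dist(X)) * matrix(runif(144, 0.95, 1.05), 12, 12)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("p", 1:12), paste0("p", 1:12))
  f1 <- nmds(D, seed = 4)
  f2 <- nmds(D, seed = 4)
  expect_identical(f1$points, f2$points)
  expect_true(all(diff(f1$stress_trace) <= 1e-12))
  # stress invariant to label permutation
  pm <- sample(12)
  f3 <- nmds(D[pm, pm], seed = 4)
  expect_equal(f3$stress, f1$stress, tolerance = 0.02)
  # zero dissimilarities are perturbed with a warning
  Dz <- D
  Dz[1, 2] <- Dz[2, 1] <- 0
  expect_warning(nmds(Dz, seed = 1), "zero")
})

test_that("nmds stress is comparable to an independent implementation", {
  skip_if_not_installed("MASS")
  set.seed(23)
  D <- random_dissimilarity(15, lo = 5, hi = 100)
  ours <- nmds(D, seed = 2)
  ref <- MASS::isoMDS(stats::as.dist(D), k = 2, trace = FALSE)
  # MASS reports stress in percent
  expect_lt(ours$stress, ref$stress / 100 + 0.02)
})

test_that("the fingerprint pipeline splits disjoint treatment pools", {
  pools <- list(
    a1 = c(100, 200, 300), a2 = c(100, 200, 300, 400),
    b1 = c(700, 800, 900), b2 = c(700, 800, 900, 1000)
  )
  res <- fingerprint_pipeline(pools, seed = 1)
  hc <- res$tree
  grp <- stats::cutree(hc, 2)
  expect_equal(unname(grp[c("a1", "a2")]), rep(grp[["a1"]], 2))
  expect_equal(unname(grp[c("b1", "b2")]), rep(grp[["b1"]], 2))
  expect_true(grp[["a1"]] != grp[["b1"]])
  expect_equal(unclass(res$dissimilarity)["a1", "b1"], 100)

  # identical profiles: degenerate matrix, MDS skipped with warning
  same <- list(x = c(100, 200), y = c(100, 200), z = c(100, 200))
  expect_warning(deg <- fingerprint_pipeline(same, seed = 1), "degenerate")
  expect_null(deg$mds)
  expect_error(fingerprint_pipeline(same[1:2]), ">= 3")

  # fixed seed reproduces MDS coordinates exactly
  b <- tiny_band_table(seed = 6)
  r1 <- suppressWarnings(fingerprint_pipeline(b, seed = 9))
  r2 <- suppressWarnings(fingerprint_pipeline(b, seed = 9))
  expect_identical(r1$mds$points, r2$mds$points)
})
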