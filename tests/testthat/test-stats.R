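test_that("spearman matches the rank formula and base R on tie-free data", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 5)
  ct <- spearman(x, y)
  expect_equal(ct$r, spearman_formula_oracle(x, y))
  expect_equal(ct$r, 0.8)
  expect_equal(ct$r, unname(cor(x, y, method = "spearman")))

  # monotone invariance and antisymmetry
  set.seed(41)
  z <- rnorm(20)
  w <- rnorm(20)
  base <- spearman(z, w)
  expect_equal(spearman(exp(z), w)$r, base$r)
  expect_equal(spearman(rev(sort(z)), sort(z))$r, -1)
  expect_equal(spearman(sort(z), sort(z))$r, 1)
  expect_error(spearman(rep(1, 10), z[1:10]), "constant")
  expect_error(spearman(1:3, 1:3), ">= 4")
})

test_that("spearman p-values are sane across the three regimes", {
  set.seed(42)
  # exact enumeration regime (n <= 7): p is a permutation tail probability
  x <- rnorm(6); y <- rnorm(6)
  ct <- spearman(x, y)
  expect_true(ct$p > 0 && ct$p <= 1)
  expect_equal(ct$method, "exact permutation")
  expect_equal((ct$p * factorial(6)) %% 1, 0, tolerance = 1e-9)
  # Monte-Carlo regime is seed-stable
  x8 <- rnorm(8); y8 <- rnorm(8)
  expect_equal(spearman(x8, y8, seed = 5)$p, spearman(x8, y8, seed = 5)$p)
  # t regime roughly matches cor.test
  x20 <- rnorm(20); y20 <- x20 + rnorm(20)
  p_ref <- cor.test(x20, y20, method = "spearman", exact = FALSE)$p.value
  expect_equal(spearman(x20, y20)$p, p_ref, tolerance = 0.05)
  # perfect monotone association keeps p in (0, 1]
  expect_gt(spearman(1:12, (1:12)^2)$p, 0)
})

test_that("repeated-measures ANOVA matches sums-of-squares arithmetic", {
  set.seed(7)
  for (i in 1:5) {
    k <- sample(3:5, 1)
    s <- sample(4:6, 1)
    d <- expand.grid(group = paste0("g", 1:k), subject = paste0("s", 1:s))
    d$y <- rnorm(nrow(d)) + as.integer(d$group) * 0.5
    fit <- rm_anova_tukey(d$y, d$group, d$subject)
    expect_equal(fit$F, rm_anova_ss_oracle(d$y, d$group, d$subject),
                 tolerance = 1e-10)
    expect_gte(fit$F, 0)
  }
})

test_that("two-group repeated-measures F equals the squared paired t", {
  set.seed(9)
  a <- rnorm(8)
  b <- a + 0.8 + rnorm(8, sd = 0.5)
  fit <- rm_anova_tukey(c(a, b), rep(c("A", "B"), each = 8),
                        rep(paste0("s", 1:8), 2))
  tt <- t.test(b, a, paired = TRUE)
  expect_equal(fit$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(fit$p, tt$p.value, tolerance = 1e-10)
})

test_that("equal group means give F = 0 and null Tukey differences", {
  set.seed(31)
  base <- rnorm(5)
  eps <- matrix(rnorm(15), 5, 3)
  eps <- eps - rowMeans(eps) - rep(colMeans(eps), each = 5) + mean(eps)
  y <- rep(base, 3) + as.numeric(eps)
  fit <- rm_anova_tukey(y, rep(c("A", "B", "C"), each = 5),
                        rep(paste0("s", 1:5), 3))
  expect_equal(fit$F, 0)
  expect_true(all(abs(fit$tukey$diff) < 1e-12))
  expect_error(rm_anova_tukey(1:5, c("A", "A", "B", "B", "B"),
                              c(1, 2, 1, 2, 3)), "unbalanced")
})

test_that("Tukey flags a strongly shifted group", {
  set.seed(11)
  hits <- 0
  for (i in 1:50) {
    d <- expand.grid(group = c("A", "B", "C"), subject = paste0("s", 1:6))
    d$y <- rnorm(nrow(d), sd = 0.5) + ifelse(d$group == "C", 3, 0)
    fit <- rm_anova_tukey(d$y, d$group, d$subject)
    pc <- fit$tukey$p.adj[grepl("C", fit$tukey$comparison)]
    if (all(pc < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 48)
})

test_that("abundance variability correlates SD with organic carbon", {
  # construction: monthly viral abundance SD proportional to organic C,
  # zero noise
  trts <- paste0("T", 1:5)
  oc <- c(1, 1.5, 2, 2.5, 3)
  rows <- list()
  for (i in seq_along(trts)) {
    for (m in seq_along(study_months())) {
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = paste(trts[i], m), treatment = trts[i],
        month = study_months()[m], plot = 1,
        viral_abundance = 1e8 + oc[i] * 1e7 * (m - 3.5),
        bacterial_abundance = 1e7)
    }
  }
  enum <- do.call(rbind, rows)
  ed <- data.frame(treatment = trts, organic_c = oc)
  av <- abundance_variability(enum, ed)
  expect_equal(av$correlation$r, 1)
  expect_equal(nrow(av$per_treatment), 5)

  # degenerate: constant abundances surface an error
  enum0 <- enum
  enum0$viral_abundance <- 1e8
  expect_error(abundance_variability(enum0, ed), "constant")
})

test_that("cca matches its unconstrained self-consistency oracle", {
  set.seed(15)
  Y <- matrix(rpois(20 * 10, lambda = 8), 20, 10)
  rownames(Y) <- paste0("s", 1:20)
  colnames(Y) <- paste0("b", 1:10)
  # unconstrained CA axis via SVD of the chi-square residuals
  P <- Y / sum(Y)
  r <- rowSums(P); cm <- colSums(P)
  Q <- (P - r %o% cm) / sqrt(r %o% cm)
  sv <- svd(Q)
  ca_sites <- sv$u[, 1] / sqrt(r)
  fit <- cca(Y, cbind(ax1 = ca_sites))
  expect_equal(fit$eigenvalues[1], sv$d[1]^2, tolerance = 1e-10)
  # eigenvalue sum bounded by total inertia
  expect_lte(sum(fit$eigenvalues), fit$total_inertia + 1e-12)
})

test_that("cca agrees with vegan and is invariant to joint permutation", {
  skip_if_not_installed("vegan")
  set.seed(16)
  Y <- matrix(rpois(24 * 12, lambda = 6) * rbinom(24 * 12, 1, 0.8), 24, 12)
  Y <- Y + 1 * (rowSums(Y) == 0)
  env <- data.frame(a = rnorm(24), b = rnorm(24), c = runif(24))
  fit <- cca(Y, env)
  ref <- vegan::cca(as.data.frame(Y) ~ a + b + c, data = env)
  expect_equal(unname(fit$eigenvalues), unname(ref$CCA$eig),
               tolerance = 1e-8)
  expect_equal(fit$total_inertia, ref$tot.chi, tolerance = 1e-8)
  pm <- sample(24)
  fit2 <- cca(Y[pm, ], env[pm, ])
  expect_equal(fit2$eigenvalues, fit$eigenvalues, tolerance = 1e-10)
  # collinear predictors are reported by name
  env2 <- env
  env2$dup <- 2 * env$a
  expect_error(cca(Y, env2), "dup|a")
  # down-weighting runs and keeps eigenvalue ordering valid
  fitdw <- cca(Y, env, downweight_rare = TRUE)
  expect_true(all(diff(fitdw$eigenvalues) <= 1e-12))
})

test_that("orthogonal environment yields near-zero constrained eigenvalues", {
  set.seed(18)
  n <- 60
  Y <- matrix(rep(c(5, 10, 15, 20, 25), n), n, 5, byrow = TRUE)
  Y <- Y * rlnorm(n * 5, 0, 0.01)
  env <- data.frame(noise = rnorm(n))
  fit <- cca(Y, env)
  expect_lt(sum(fit$eigenvalues) / fit$total_inertia, 0.2)
})

test_that("the permutation test is deterministic and add-one bounded", {
  set.seed(20)
  Y <- matrix(rpois(18 * 8, 5), 18, 8)
  Y <- Y + 1 * (rowSums(Y) == 0)
  env <- data.frame(x = rnorm(18))
  p1 <- cca_permutation_test(Y, env, n_perm = 99, seed = 3)$p
  p2 <- cca_permutation_test(Y, env, n_perm = 99, seed = 3)$p
  expect_identical(p1, p2)
  expect_gte(p1, 1 / 100)
  expect_lte(p1, 1)
  expect_error(cca_permutation_test(Y, env, n_perm = 10), ">= 99")
})
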