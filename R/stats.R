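#' Spearman rank correlation with small-sample permutation p-values
#'
#' The coefficient is the Pearson correlation of mid-ranks (average ranks for
#' ties), computed on pairwise-complete observations. Two-sided significance
#' uses the t approximation for n >= 10; for smaller n the permutation null is
#' used directly — full enumeration for n <= 7, otherwise `n_mc` Monte-Carlo
#' permutations with the add-one convention.
#'
#' @param x,y Numeric vectors of equal length (n >= 4 complete pairs).
#' @param n_mc Monte-Carlo permutations for 7 < n < 10.
#' @param seed Seed for the Monte-Carlo branch.
#' @return A list of class `correlation_result`: `r`, `p`, `n`, `method`.
#' @export
spearman <- function(x, y, n_mc = 10000, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need >= 4 complete pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("undefined correlation: constant vector")
  }
  r <- stats::cor(rx, ry)
  if (n >= 10) {
    r2 <- min(r^2, 1 - 1e-15)
    tstat <- r * sqrt((n - 2) / (1 - r2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t-approximation"
  } else if (n <= 7) {
    perms <- all_permutations(n)
    rp <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rp) >= abs(r) - 1e-12)
    method <- "exact permutation"
  } else {
    p <- with_seed(seed, {
      rp <- replicate(n_mc, stats::cor(rx, ry[sample.int(n)]))
      (1 + sum(abs(rp) >= abs(r) - 1e-12)) / (1 + n_mc)
    })
    method <- "Monte-Carlo permutation"
  }
  p <- max(min(p, 1), .Machine$double.xmin)
  structure(list(r = r, p = p, n = n, method = method),
            class = "correlation_result")
}

# all permutations of 1..n as a matrix (n! rows); feasible for n <= 7
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (i in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[i, ] + (sub[i, ] >= pos), pos, after = pos - 1)[
        seq_len(n)]
      row <- row + 1L
    }
  }
  out
}

#' One-way repeated-measures ANOVA with Tukey HSD post-hoc
#'
#' Fits the additive within-subjects model value ~ group + subject, whose
#' residual mean square is the group-by-subject interaction — the error term
#' of the one-way repeated-measures F test. Pairwise comparisons use Tukey's
#' honestly-significant-difference procedure on the same error term.
#'
#' @param values Numeric response.
#' @param groups Group (within-subject condition) labels.
#' @param subjects Subject (replicate plot) labels; the design must be a
#'   complete, balanced subjects x groups crossing.
#' @return A list of class `rm_anova`: `F`, `df1`, `df2`, `p`, and `tukey`
#'   (data frame with pairwise differences, intervals and adjusted p-values).
#' @export
rm_anova_tukey <- function(values, groups, subjects) {
  groups <- factor(groups)
  subjects <- factor(subjects)
  tab <- table(subjects, groups)
  if (any(tab != 1)) {
    stop("unbalanced design: each subject must appear exactly once per ",
         "group; complete cases listwise before calling")
  }
  fit <- stats::aov(values ~ groups + subjects)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, "groups")$groups
  structure(list(
    F = an["groups", "F value"],
    df1 = an["groups", "Df"],
    df2 = an["Residuals", "Df"],
    p = an["groups", "Pr(>F)"],
    tukey = data.frame(comparison = rownames(tk), tk, row.names = NULL)
  ), class = "rm_anova")
}

#' Seasonal abundance variability versus organic carbon
#'
#' For each treatment: the sample standard deviation of viral abundance
#' across monthly means (plots averaged within month), paired with the
#' treatment's mean organic carbon content, and the Spearman correlation
#' between the two across treatments.
#'
#' @param enumeration Enumeration study table.
#' @param edaphics Edaphics study table (column `organic_c`).
#' @return A list of class `variability_result`: `per_treatment` (data frame
#'   with `treatment`, `sd_viral_abundance`, `mean_organic_c`) and
#'   `correlation` (a [spearman()] result).
#' @export
abundance_variability <- function(enumeration, edaphics) {
  trts <- unique(as.character(enumeration$treatment))
  per <- do.call(rbind, lapply(trts, function(tr) {
    e <- enumeration[enumeration$treatment == tr, , drop = FALSE]
    monthly <- tapply(e$viral_abundance, as.character(e$month), mean)
    if (length(monthly) < 3) stop("need >= 3 months per treatment")
    oc <- mean(edaphics$organic_c[edaphics$treatment == tr])
    data.frame(treatment = tr,
               sd_viral_abundance = stats::sd(monthly),
               mean_organic_c = oc)
  }))
  corr <- spearman(per$sd_viral_abundance, per$mean_organic_c)
  structure(list(per_treatment = per, correlation = corr),
            class = "variability_result")
}
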