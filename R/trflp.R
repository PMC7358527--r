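#' Align replicate T-RFLP profiles by peak size
#'
#' Greedy left-to-right grouping of the pooled replicate peaks: peaks join the
#' current group while they lie within `tol` nucleotides of the group's
#' running mean size, otherwise a new group is opened. Each peak belongs to at
#' most one group.
#'
#' @param peaks A `data.frame` with columns `replicate`, `size` (nt) and
#'   `height` (fluorescence units).
#' @param tol Alignment tolerance in nucleotides (> 0).
#' @return `peaks` sorted by size with an integer `group` column appended.
#' @export
align_replicates <- function(peaks, tol = 0.5) {
  if (tol <= 0) stop("tol must be > 0")
  p <- peaks[order(peaks$size, peaks$replicate), , drop = FALSE]
  n <- nrow(p)
  group <- integer(n)
  if (n > 0) {
    g <- 1L
    group[1] <- 1L
    msum <- p$size[1]
    cnt <- 1L
    for (i in seq_len(n)[-1]) {
      if (abs(p$size[i] - msum / cnt) <= tol) {
        group[i] <- g
        msum <- msum + p$size[i]
        cnt <- cnt + 1L
      } else {
        g <- g + 1L
        group[i] <- g
        msum <- p$size[i]
        cnt <- 1L
      }
    }
  }
  p$group <- group
  rownames(p) <- NULL
  p
}

#' Keep only peaks reproduced in every replicate
#'
#' A peak group is reproducible when it contains exactly one peak from each of
#' the `n_reps` replicates; all other groups (missing from a replicate, or
#' containing a double peak from one replicate) are removed.
#'
#' @param aligned Output of [align_replicates()].
#' @param n_reps Number of replicate profiles.
#' @return The reproducible subset of `aligned`.
#' @export
filter_reproducible <- function(aligned, n_reps) {
  if (nrow(aligned) == 0) return(aligned)
  keep <- vapply(split(aligned$replicate, aligned$group), function(r) {
    length(r) == n_reps && length(unique(r)) == n_reps
  }, logical(1))
  ok <- as.integer(names(keep)[keep])
  aligned[aligned$group %in% ok, , drop = FALSE]
}

#' Reiteratively normalise replicate total fluorescence
#'
#' Iterates: scale every replicate's peak heights by (minimum replicate total
#' fluorescence) / (own total); delete peaks falling below
#' `minor_frac` of their profile's new total; recompute totals. Stops when a
#' full pass deletes nothing. On exit all totals equal the minimum total and
#' no retained peak is below the detection threshold.
#'
#' @param peaks A `data.frame` with columns `replicate` and `height` (other
#'   columns pass through).
#' @param minor_frac Relative detection threshold (default 0.001, i.e. 0.1%
#'   of total trace fluorescence).
#' @return The scaled, thresholded `peaks`.
#' @export
normalize_reiterative <- function(peaks, minor_frac = 0.001) {
  totals <- tapply(peaks$height, peaks$replicate, sum)
  if (all(totals == 0)) stop("degenerate input: all replicate totals are zero")
  repeat {
    totals <- tapply(peaks$height, peaks$replicate, sum)
    m <- min(totals[totals > 0])
    scale <- m / totals[as.character(peaks$replicate)]
    peaks$height <- peaks$height * as.numeric(scale)
    keep <- peaks$height >= minor_frac * m
    if (all(keep)) break
    peaks <- peaks[keep, , drop = FALSE]
    if (nrow(peaks) == 0) stop("degenerate input: all peaks below threshold")
  }
  rownames(peaks) <- NULL
  peaks
}

#' Remove minor peaks from a profile
#'
#' Drops peaks whose height is strictly less than `minor_frac` of the
#' profile's total fluorescence (total computed before removal). A peak at
#' exactly the threshold is retained.
#'
#' @param profile A `data.frame` with a `height` column.
#' @param minor_frac Fraction of total trace fluorescence in (0, 1).
#' @return The filtered profile.
#' @export
remove_minor_peaks <- function(profile, minor_frac = 0.001) {
  if (minor_frac <= 0 || minor_frac >= 1) stop("minor_frac must be in (0,1)")
  if (nrow(profile) == 0) return(profile)
  total <- sum(profile$height)
  out <- profile[profile$height >= minor_frac * total, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a consensus profile from reproducible peak groups
#'
#' Per group, the unweighted mean of peak size and of peak height across
#' replicates, with the number of supporting replicates recorded.
#'
#' @param aligned Filtered output of [filter_reproducible()] (columns
#'   `size`, `height`, `group`).
#' @return A `data.frame` with `size`, `height`, `support`, sorted by size.
#' @export
consensus <- function(aligned) {
  if (nrow(aligned) == 0) {
    return(data.frame(size = numeric(0), height = numeric(0),
                      support = integer(0)))
  }
  sp <- split(aligned, aligned$group)
  out <- data.frame(
    size = vapply(sp, function(g) mean(g$size), numeric(1)),
    height = vapply(sp, function(g) mean(g$height), numeric(1)),
    support = vapply(sp, nrow, integer(1))
  )
  out <- out[order(out$size), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Bin consensus peaks across samples
#'
#' Pools every sample's consensus peaks, sorts by size, and opens a new bin
#' whenever the next peak lies more than `tol` nucleotides from the current
#' bin's running mean (greedy left-to-right; a peak at exactly the tolerance
#' joins the earlier bin). The returned matrix holds relative fluorescence
#' fractions (each row sums to 1 over non-empty profiles); bin representatives
#' are the mean member sizes.
#'
#' @param profiles A `data.frame` with columns `sample_id`, `size`, `height`
#'   (e.g. stacked [consensus()] outputs).
#' @param tol Binning tolerance in nucleotides (default 0.5).
#' @return A list of class `bin_table` with `bins` (representative sizes) and
#'   `matrix` (samples x bins relative abundances).
#' @export
bin_across_samples <- function(profiles, tol = 0.5) {
  if (tol <= 0) stop("tol must be > 0")
  p <- profiles[order(profiles$size), , drop = FALSE]
  n <- nrow(p)
  bin <- integer(n)
  if (n > 0) {
    b <- 1L
    bin[1] <- 1L
    msum <- p$size[1]
    cnt <- 1L
    for (i in seq_len(n)[-1]) {
      if (abs(p$size[i] - msum / cnt) <= tol) {
        bin[i] <- b
        msum <- msum + p$size[i]
        cnt <- cnt + 1L
      } else {
        b <- b + 1L
        bin[i] <- b
        msum <- p$size[i]
        cnt <- 1L
      }
    }
  }
  p$bin <- bin
  bins <- vapply(split(p$size, p$bin), mean, numeric(1))
  samples <- unique(as.character(profiles$sample_id))
  mat <- matrix(0, nrow = length(samples), ncol = length(bins),
                dimnames = list(samples, sprintf("%.2f", bins)))
  for (i in seq_len(n)) {
    mat[as.character(p$sample_id[i]), p$bin[i]] <-
      mat[as.character(p$sample_id[i]), p$bin[i]] + p$height[i]
  }
  rs <- rowSums(mat)
  mat[rs > 0, ] <- mat[rs > 0, , drop = FALSE] / rs[rs > 0]
  structure(list(bins = unname(bins), matrix = mat), class = "bin_table")
}

#' Shannon diversity of a relative-abundance vector
#'
#' H = -sum p_i log p_i over non-zero entries after renormalisation. Natural
#' log by default, matching the usual community-profile convention.
#'
#' @param row Non-negative abundances with positive sum.
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return Shannon diversity H.
#' @export
shannon_diversity <- function(row, base = exp(1)) {
  if (any(row < 0)) stop("abundances must be >= 0")
  if (sum(row) <= 0) stop("undefined diversity: all-zero abundance row")
  as.numeric(vegan::diversity(row, index = "shannon", base = base))
}

#' Full T-RFLP replicate-consensus pipeline
#'
#' Stage order: align replicates by size, remove peaks not reproduced in all
#' replicates, reiteratively normalise total fluorescence (applying the
#' relative detection threshold), remove remaining minor peaks, drop groups
#' broken by the thresholding, average to a consensus profile per sample,
#' bin consensus peaks across samples, and compute per-sample Shannon
#' diversity.
#'
#' @param peaks A peaks study table: columns `sample_id`, `replicate`, `size`,
#'   `height`.
#' @param align_tol Replicate alignment tolerance, nt.
#' @param bin_tol Cross-sample binning tolerance, nt.
#' @param minor_frac Relative detection threshold.
#' @return A list of class `trflp_result`: `bin_table`, `diversity`
#'   (per-sample H), `consensus` (stacked consensus profiles), and `qc`
#'   (peaks removed per rule, peaks per profile, unique TRF count).
#' @export
trflp_pipeline <- function(peaks, align_tol = 0.5, bin_tol = 0.5,
                           minor_frac = 0.001) {
  samples <- unique(as.character(peaks$sample_id))
  qc <- list(irreproducible_removed = 0L, subthreshold_removed = 0L)
  cons_list <- list()
  for (s in samples) {
    ps <- peaks[peaks$sample_id == s, , drop = FALSE]
    n_reps <- length(unique(ps$replicate))
    al <- align_replicates(ps, tol = align_tol)
    fi <- filter_reproducible(al, n_reps)
    qc$irreproducible_removed <- qc$irreproducible_removed +
      (nrow(al) - nrow(fi))
    if (nrow(fi) == 0) next
    no <- normalize_reiterative(fi, minor_frac = minor_frac)
    no <- do.call(rbind, lapply(split(no, no$replicate), remove_minor_peaks,
                                minor_frac = minor_frac))
    qc$subthreshold_removed <- qc$subthreshold_removed + (nrow(fi) - nrow(no))
    # thresholding may break reproducibility; re-enforce it
    no <- filter_reproducible(no, n_reps)
    co <- consensus(no)
    if (nrow(co) == 0) next
    co$sample_id <- s
    cons_list[[s]] <- co
  }
  if (length(cons_list) == 0) stop("no consensus peaks survived filtering")
  cons <- do.call(rbind, cons_list)
  rownames(cons) <- NULL
  bt <- bin_across_samples(cons, tol = bin_tol)
  h <- apply(bt$matrix, 1, function(r) {
    if (sum(r) > 0) shannon_diversity(r) else NA_real_
  })
  qc$peaks_per_profile <- as.numeric(table(cons$sample_id)[samples])
  names(qc$peaks_per_profile) <- samples
  qc$mean_peaks_per_profile <- mean(qc$peaks_per_profile, na.rm = TRUE)
  qc$unique_trfs <- length(bt$bins)
  structure(list(bin_table = bt, diversity = h, consensus = cons, qc = qc),
            class = "trflp_result")
}
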