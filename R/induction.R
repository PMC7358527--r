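#' Construct an induction-assay table
#'
#' An induction assay yields four epifluorescence counts per sample: viral and
#' bacterial abundance in an untreated control tube (`v_control`, `b_control`)
#' and in a mitomycin-C-treated tube (`v_mitc`, `b_mitc`), all per gram of dry
#' soil after the overnight incubation.
#'
#' @param v_control,v_mitc Viral counts (VLP g^-1), control and mitC tube.
#' @param b_control,b_mitc Bacterial counts (cells g^-1), control and mitC tube.
#' @return A `data.frame` of class `induction_assay`.
#' @export
induction_assay <- function(v_control, v_mitc, b_control, b_mitc) {
  counts <- list(v_control = v_control, v_mitc = v_mitc,
                 b_control = b_control, b_mitc = b_mitc)
  for (nm in names(counts)) {
    if (any(counts[[nm]] < 0, na.rm = TRUE)) stop(nm, " must be >= 0")
  }
  out <- data.frame(counts)
  class(out) <- c("induction_assay", "data.frame")
  out
}

#' Virus-to-bacteria ratio
#'
#' @param va Viral abundance (VLP g^-1).
#' @param ba Bacterial abundance (cells g^-1); must be positive.
#' @return `va / ba`.
#' @export
virus_bacteria_ratio <- function(va, ba) {
  if (any(ba <= 0)) stop("undefined ratio: bacterial abundance must be > 0")
  va / ba
}

#' Estimate burst size from an induction assay
#'
#' Burst size is estimated as the viruses released per lysed cell,
#' BZ = (Vm - Vc) / (Bc - Bm). The estimate is undefined when no induction is
#' seen (Vm <= Vc) or when growth of non-induced cells dominates (Bm >= Bc);
#' defined estimates below one virus per lysed cell are flagged `low_burst`
#' rather than discarded, since they are the quality-control signal that the
#' assay incubation allowed substantial growth.
#'
#' @param assay An [induction_assay()] table (or data frame with the same
#'   columns); vectorised over rows.
#' @return A `data.frame` with columns `bz_calc` (NA when undefined) and the
#'   logical flags `no_induction`, `growth_dominated`, `low_burst`.
#' @export
estimate_burst_size <- function(assay) {
  dv <- assay$v_mitc - assay$v_control
  db <- assay$b_control - assay$b_mitc
  no_induction <- dv <= 0
  growth_dominated <- db <= 0
  bz <- ifelse(dv > 0 & db > 0, dv / db, NA_real_)
  data.frame(
    bz_calc = bz,
    no_induction = no_induction,
    growth_dominated = growth_dominated,
    low_burst = !is.na(bz) & bz < 1
  )
}

#' Inducible fraction using the calculated burst size
#'
#' IF = 100 * ((Vm - Vc) / BZ) / Bc with BZ the calculated burst size.
#' Substituting BZ = (Vm - Vc)/(Bc - Bm) shows that, whenever BZ is defined,
#' this reduces algebraically to 100 * (Bc - Bm) / Bc: the fraction of control
#' cells lysed by induction.
#'
#' @inheritParams estimate_burst_size
#' @return Numeric vector of percentages; NA where the burst size (and hence
#'   IF) is undefined.
#' @export
inducible_fraction_calculated <- function(assay) {
  if (any(assay$b_control <= 0)) {
    stop("undefined denominator: b_control must be > 0")
  }
  bz <- estimate_burst_size(assay)
  dv <- assay$v_mitc - assay$v_control
  ifelse(is.na(bz$bz_calc), NA_real_,
         100 * (dv / bz$bz_calc) / assay$b_control)
}

#' Inducible fraction using an assumed burst size
#'
#' IF = 100 * ((Vm - Vc) / assumed_bz) / Bc. The conventional assumed burst
#' size is 20 viruses per lysed cell (the default), in which case the
#' statistic is usually written IF20. A negative viral delta yields a
#' negative value (reported, not clipped) so that failed inductions remain
#' visible in summaries.
#'
#' @inheritParams estimate_burst_size
#' @param assumed_bz Assumed burst size, viruses per lysed cell (> 0).
#' @return Numeric vector of percentages.
#' @export
inducible_fraction_assumed <- function(assay, assumed_bz = 20) {
  if (assumed_bz <= 0) stop("assumed_bz must be > 0")
  if (any(assay$b_control <= 0)) {
    stop("undefined denominator: b_control must be > 0")
  }
  dv <- assay$v_mitc - assay$v_control
  100 * (dv / assumed_bz) / assay$b_control
}

#' Percent increase in viral abundance upon induction
#'
#' 100 * (Vm - Vc) / Vc: a qualitative induction measure that needs no burst
#' size assumption.
#'
#' @inheritParams estimate_burst_size
#' @return Numeric vector of percentages.
#' @export
percent_induction_increase <- function(assay) {
  if (any(assay$v_control <= 0)) {
    stop("undefined baseline: v_control must be > 0")
  }
  100 * (assay$v_mitc - assay$v_control) / assay$v_control
}

#' Per-assay induction statistics
#'
#' Convenience wrapper computing every per-assay statistic at once.
#'
#' @inheritParams inducible_fraction_assumed
#' @return A `data.frame` with `delta_v`, `bz_calc`, `if_calc`, `if_assumed`,
#'   `pct_increase` and the three flags.
#' @export
induction_stats <- function(assay, assumed_bz = 20) {
  bz <- estimate_burst_size(assay)
  data.frame(
    delta_v = assay$v_mitc - assay$v_control,
    bz_calc = bz$bz_calc,
    if_calc = inducible_fraction_calculated(assay),
    if_assumed = inducible_fraction_assumed(assay, assumed_bz),
    pct_increase = percent_induction_increase(assay),
    no_induction = bz$no_induction,
    growth_dominated = bz$growth_dominated,
    low_burst = bz$low_burst
  )
}

#' Summarise induction statistics by treatment and month
#'
#' Means and sample standard deviations across plot replicates for each
#' (treatment, month) group. Groups with a single plot report the value with
#' SD absent (`NA`), mirroring an unreplicated site; empty groups are skipped
#' with a warning.
#'
#' @param table An induction study table (see [read_study_table()]).
#' @param assumed_bz Assumed burst size passed to [inducible_fraction_assumed()].
#' @return A `data.frame` with one row per (treatment, month) and
#'   `<stat>_mean` / `<stat>_sd` columns plus `n_plots` and flag counts.
#' @export
summarize_induction <- function(table, assumed_bz = 20) {
  stats_cols <- c("bz_calc", "if_calc", "if_assumed", "pct_increase")
  per <- induction_stats(
    induction_assay(table$v_control, table$v_mitc,
                    table$b_control, table$b_mitc),
    assumed_bz = assumed_bz
  )
  per$treatment <- table$treatment
  per$month <- table$month
  groups <- unique(per[, c("treatment", "month")])
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- per[per$treatment == groups$treatment[i] &
               per$month == groups$month[i], , drop = FALSE]
    if (nrow(g) == 0) {
      warning("empty group skipped: ", groups$treatment[i], "/",
              groups$month[i])
      return(NULL)
    }
    out <- data.frame(treatment = groups$treatment[i],
                      month = groups$month[i], n_plots = nrow(g))
    for (s in stats_cols) {
      v <- g[[s]][!is.na(g[[s]])]
      out[[paste0(s, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      out[[paste0(s, "_sd")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    out$n_flagged <- sum(g$low_burst | g$growth_dominated)
    out
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
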