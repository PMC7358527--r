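#' Default months of the sampling season
#'
#' Ordered design levels (not dates): May through November with August
#' unsampled, six levels in all.
#'
#' @return Character vector of month labels.
#' @export
study_months <- function() {
  c("May", "June", "July", "September", "October", "November")
}

#' Generator parameters for a synthetic field study
#'
#' Defaults emulate a five-treatment (two agricultural, two early-successional,
#' one unreplicated forest site), six-month, triplicate-plot design. Counts
#' carry multiplicative lognormal noise (microscopy counts are positive and
#' span orders of magnitude); log-abundance depends log-linearly on organic
#' carbon; the month-to-month variability of viral abundance scales with
#' organic carbon so that seasonal SD and carbon content are positively
#' linked. Induction assays have a latent per-treatment lysogen fraction and
#' burst size; non-induced growth acts equally on control and treated tubes.
#'
#' @param treatments Treatment labels.
#' @param months Ordered month labels.
#' @param plots_per_treatment Integer replicate plots per treatment (the last
#'   treatment defaults to a single, unreplicated plot).
#' @param mean_bacterial_abundance Lognormal median bacterial abundance,
#'   cells g^-1.
#' @param mean_vbr Mean virus-to-bacteria ratio in soil.
#' @param count_cv Coefficient of variation of count noise.
#' @param lysogen_fraction Per-treatment inducible lysogen fraction in
#'   \[0, 1\] (recycled).
#' @param burst_size Latent burst size, viruses per lysed cell (> 0).
#' @param noninduced_growth Multiplicative growth factor (>= 1) applied to
#'   both tubes' bacterial counts over the incubation.
#' @param tube_vbr Control-tube viral baseline as a fraction of the cell
#'   count (the washed cell suspension starts nearly virus-free).
#' @param organic_c_by_treatment Percent organic carbon by mass per treatment.
#' @param abundance_c_slope Log-linear effect of organic carbon (per % C) on
#'   abundance.
#' @param seasonal_va_sd Log-scale SD of monthly viral-abundance effects at
#'   the mean carbon content; scaled per treatment by its relative carbon.
#' @param community_size Taxa per community.
#' @param community_concentration Dirichlet concentration of the base
#'   community (high enough that taxa stay above the 0.1% detection floor).
#' @param treatment_divergence,seasonal_drift,plot_heterogeneity Mixture
#'   weights in \[0, 1\] controlling how far treatment, month and plot
#'   communities move from their parent community.
#' @param trflp_reps Replicate PCRs per sample.
#' @param total_fluorescence Total trace fluorescence per replicate.
#' @param height_cv Peak-height noise CV.
#' @param dropout Per-peak dropout probability per replicate.
#' @param size_jitter_sd Fragment-size jitter SD, nt.
#' @param band_pool_size Number of possible fingerprint band positions.
#' @param band_core_richness Bands in a treatment's core set.
#' @param band_core_divergence Perturbation rate between the global band core
#'   and each treatment's core.
#' @param band_turnover_free,band_turnover_induced Per-band monthly flip
#'   probability for free extracellular and mitC-induced viral assemblages.
#' @param band_plot_heterogeneity Per-band flip probability between plots.
#' @return A list of class `generator_params`.
#' @export
generator_params <- function(
    treatments = c("T1", "T4", "T7", "T8", "SF2"),
    months = study_months(),
    plots_per_treatment = c(3, 3, 3, 3, 1),
    mean_bacterial_abundance = 5e8,
    mean_vbr = 5,
    count_cv = 0.3,
    lysogen_fraction = 0.02,
    burst_size = 20,
    noninduced_growth = 1.2,
    tube_vbr = 0.1,
    organic_c_by_treatment = c(0.9, 1.1, 1.4, 1.9, 2.8),
    abundance_c_slope = 0.5,
    seasonal_va_sd = 0.4,
    community_size = 30,
    community_concentration = 5,
    treatment_divergence = 0.6,
    seasonal_drift = 0.1,
    plot_heterogeneity = 0.05,
    trflp_reps = 3,
    total_fluorescence = 50000,
    height_cv = 0.1,
    dropout = 0.02,
    size_jitter_sd = 0.15,
    band_pool_size = 60,
    band_core_richness = 25,
    band_core_divergence = 0.12,
    band_turnover_free = 0.05,
    band_turnover_induced = 0.15,
    band_plot_heterogeneity = 0.05) {
  p <- as.list(environment())
  nt <- length(p$treatments)
  if (nt < 1 || length(p$months) < 1) stop("degenerate design")
  p$plots_per_treatment <- rep_len(as.integer(p$plots_per_treatment), nt)
  if (any(p$plots_per_treatment < 1)) stop("degenerate design: 0 plots")
  p$lysogen_fraction <- rep_len(p$lysogen_fraction, nt)
  p$organic_c_by_treatment <- rep_len(p$organic_c_by_treatment, nt)
  frac_pars <- c("count_cv", "height_cv", "dropout", "treatment_divergence",
                 "seasonal_drift", "plot_heterogeneity",
                 "band_turnover_free", "band_turnover_induced",
                 "band_plot_heterogeneity")
  for (nm in frac_pars) {
    if (any(p[[nm]] < 0) || any(p[[nm]] > 1)) stop(nm, " must be in [0,1]")
  }
  if (any(p$lysogen_fraction < 0 | p$lysogen_fraction > 1)) {
    stop("lysogen_fraction must be in [0,1]")
  }
  if (p$burst_size <= 0) stop("burst_size must be > 0")
  if (p$noninduced_growth < 1) stop("noninduced_growth must be >= 1")
  if (p$size_jitter_sd < 0) stop("size_jitter_sd must be >= 0")
  structure(p, class = "generator_params")
}

#' Simulate one mitomycin-C induction assay
#'
#' Latent model: lysed cells L = `true_if * bc`; before noise,
#' Vm = Vc + burst * L, Bm = (bc - L) * growth, Bc = bc * growth (growth acts
#' equally on both tubes). Each of the four counts then receives independent
#' multiplicative lognormal noise with unit mean and coefficient of variation
#' `cv`.
#'
#' @param true_if True inducible lysogen fraction in \[0, 1\].
#' @param burst Burst size, viruses per lysed cell.
#' @param bc Starting bacterial count, cells g^-1 (> 0).
#' @param growth Non-induced growth factor (>= 1).
#' @param cv Count-noise coefficient of variation (>= 0).
#' @param seed Seed; `NULL` uses the current RNG stream.
#' @param vc Control-tube viral baseline count (default `0.1 * bc`).
#' @param n Number of assays to draw.
#' @return An [induction_assay()] table with `n` rows.
#' @export
generate_induction_assay <- function(true_if, burst, bc, growth = 1,
                                     cv = 0, seed = NULL, vc = 0.1 * bc,
                                     n = 1) {
  if (true_if < 0 || true_if > 1) stop("true_if must be in [0,1]")
  if (bc <= 0) stop("bc must be > 0")
  if (cv < 0) stop("cv must be >= 0")
  with_seed(seed, {
    L <- true_if * bc
    v_control <- vc * rlnorm_cv(n, cv)
    v_mitc <- (vc + burst * L) * rlnorm_cv(n, cv)
    b_control <- bc * growth * rlnorm_cv(n, cv)
    b_mitc <- (bc - L) * growth * rlnorm_cv(n, cv)
    induction_assay(v_control, v_mitc, b_control, b_mitc)
  })
}

#' Simulate replicate T-RFLP peak profiles for one community
#'
#' Peak heights are proportional to the community relative abundances times
#' the total trace fluorescence, with multiplicative lognormal noise of CV
#' `height_cv`; fragment sizes are jittered N(0, size_jitter_sd^2) per
#' replicate; peaks drop out independently at rate `dropout`.
#'
#' @param community Relative-abundance vector summing to 1.
#' @param taxon_sizes Fragment sizes (nt), pairwise separated by more than
#'   twice the intended binning tolerance.
#' @param total_fluorescence Target total fluorescence per replicate.
#' @param n_reps Number of replicates.
#' @param size_jitter_sd Size jitter SD (nt).
#' @param dropout Per-peak dropout probability.
#' @param height_cv Height-noise CV.
#' @param seed Seed.
#' @param bin_tol Binning tolerance used for the separation check.
#' @return A `data.frame` with columns `replicate`, `size`, `height`.
#' @export
generate_trflp_replicates <- function(community, taxon_sizes,
                                      total_fluorescence = 50000,
                                      n_reps = 3, size_jitter_sd = 0,
                                      dropout = 0, height_cv = 0,
                                      seed = NULL, bin_tol = 0.5) {
  if (abs(sum(community) - 1) > 1e-8) stop("community must sum to 1")
  if (length(community) != length(taxon_sizes)) {
    stop("community and taxon_sizes must have equal length")
  }
  if (min(diff(sort(taxon_sizes))) <= 2 * bin_tol) {
    stop("size collision: taxon sizes must be separated by > 2 * bin_tol")
  }
  with_seed(seed, {
    out <- lapply(seq_len(n_reps), function(r) {
      keep <- stats::runif(length(community)) >= dropout
      h <- community * total_fluorescence * rlnorm_cv(length(community),
                                                      height_cv)
      s <- taxon_sizes + stats::rnorm(length(community), 0, size_jitter_sd)
      data.frame(replicate = r, size = s[keep & h > 0],
                 height = h[keep & h > 0])
    })
    do.call(rbind, out)
  })
}

#' Simulate fingerprint band profiles for a (month, site) design
#'
#' A global core band set is drawn from the positional pool; each treatment's
#' core is a richness-preserving perturbation of it at rate
#' `core_divergence`, so assemblages share most bands across land uses (as
#' fingerprints of related soil viral communities do) while remaining
#' separable. Each treatment's first-month profile is its core, and each
#' subsequent month membership
#' turns over in a richness-preserving way: each present band is lost with
#' probability `turnover`, and each absent position is gained with the
#' balancing probability `turnover * richness / (pool - richness)`, so
#' expected richness is stationary and adjacent months stay most similar.
#' Turnover decisions compare a fixed stream of uniforms against the
#' turnover-scaled thresholds, so two calls with the same seed and different
#' turnover values yield nested change sets — raising turnover can only add
#' month-to-month change.
#'
#' @param treatments Treatment labels.
#' @param months Ordered month labels.
#' @param pool_size Number of candidate band positions (> 0).
#' @param core_richness Bands in each treatment's core set.
#' @param core_divergence Per-band perturbation rate between the global core
#'   and each treatment core.
#' @param turnover Per-band monthly flip probability in \[0, 1\].
#' @param plot_heterogeneity Unused at the pooled (month, site) level;
#'   accepted for interface symmetry with per-plot profiles.
#' @param seed Seed.
#' @return A bands study table: `label`, `treatment`, `month`, `position`.
#' @export
generate_band_profiles <- function(treatments, months, pool_size = 60,
                                   core_richness = 25, core_divergence = 0.12,
                                   turnover = 0.05,
                                   plot_heterogeneity = 0, seed = NULL) {
  if (pool_size < 1) stop("empty band pool")
  if (turnover < 0 || turnover > 1) stop("turnover must be in [0,1]")
  if (core_divergence < 0 || core_divergence > 1) {
    stop("core_divergence must be in [0,1]")
  }
  if (core_richness > pool_size) stop("core_richness exceeds pool size")
  # pool positions: log-spaced over a typical gel range (100-1500 bp), spread
  # apart so a 2% matching tolerance keeps them distinct
  pool <- round(exp(seq(log(100), log(1500), length.out = pool_size)), 1)
  step_state <- function(state, rate) {
    u <- stats::runif(pool_size)
    k <- sum(state)
    gain_p <- if (k < pool_size) min(1, rate * k / (pool_size - k)) else 0
    (state & !(state & u < rate)) | (!state & u < gain_p)
  }
  with_seed(seed, {
    global_core <- logical(pool_size)
    global_core[sample.int(pool_size, core_richness)] <- TRUE
    rows <- list()
    for (tr in treatments) {
      state <- step_state(global_core, core_divergence)
      for (mi in seq_along(months)) {
        if (mi > 1) state <- step_state(state, turnover)
        if (!any(state)) state[sample.int(pool_size, 1)] <- TRUE
        rows[[length(rows) + 1]] <- data.frame(
          label = paste(months[mi], tr, sep = "_"),
          treatment = tr, month = months[mi],
          position = pool[state]
        )
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a complete synthetic study
#'
#' Produces the five study tables (enumeration, induction, T-RFLP peaks,
#' fingerprint bands for free and induced assemblages, edaphics) plus the
#' latent ground truth, all as a pure function of `(params, seed)`.
#'
#' @param params A [generator_params()] list.
#' @param seed Integer seed.
#' @return A list of class `synthetic_study` with elements `enumeration`,
#'   `induction`, `peaks`, `bands_free`, `bands_induced`, `edaphics`,
#'   `truth`, `params`, `seed`.
#' @export
generate_study <- function(params = generator_params(), seed = 1) {
  p <- params
  nt <- length(p$treatments)
  mean_oc <- mean(p$organic_c_by_treatment)
  with_seed(seed, {
    # taxon fragment sizes: distinct integers spaced >= 2 nt (> 2 * 0.5 tol)
    taxon_sizes <- sort(sample(seq(60L, 598L, by = 2L), p$community_size))
    base_comm <- rdirichlet1(rep(p$community_concentration, p$community_size))
    sdlog <- lnorm_sdlog(p$count_cv)

    enum <- list(); induc <- list(); peaks <- list(); edaph <- list()
    truth_comm <- list()
    for (ti in seq_len(nt)) {
      tr <- p$treatments[ti]
      oc <- p$organic_c_by_treatment[ti]
      comm_t <- {
        u <- rdirichlet1(rep(p$community_concentration, p$community_size))
        v <- (1 - p$treatment_divergence) * base_comm +
          p$treatment_divergence * u
        v / sum(v)
      }
      # monthly viral-abundance effects: SD grows with relative carbon
      va_month_sd <- p$seasonal_va_sd * oc / mean_oc
      va_month_eff <- stats::rnorm(length(p$months), 0, va_month_sd)
      comm_m <- comm_t
      for (mi in seq_along(p$months)) {
        mo <- p$months[mi]
        if (mi > 1) {
          u <- rdirichlet1(rep(p$community_concentration, p$community_size))
          comm_m <- (1 - p$seasonal_drift) * comm_m + p$seasonal_drift * u
          comm_m <- comm_m / sum(comm_m)
        }
        for (pl in seq_len(p$plots_per_treatment[ti])) {
          sid <- paste(tr, mo, pl, sep = "_")
          comm_p <- if (p$plot_heterogeneity > 0) {
            u <- rdirichlet1(rep(p$community_concentration,
                                 p$community_size))
            v <- (1 - p$plot_heterogeneity) * comm_m +
              p$plot_heterogeneity * u
            v / sum(v)
          } else comm_m
          truth_comm[[sid]] <- comm_p

          ba <- p$mean_bacterial_abundance *
            exp(p$abundance_c_slope * (oc - mean_oc)) *
            rlnorm_cv(1, p$count_cv)
          va <- ba * p$mean_vbr * exp(va_month_eff[mi]) *
            rlnorm_cv(1, p$count_cv)
          enum[[sid]] <- data.frame(
            sample_id = sid, treatment = tr, month = mo, plot = pl,
            viral_abundance = va, bacterial_abundance = ba
          )

          assay <- generate_induction_assay(
            true_if = p$lysogen_fraction[ti], burst = p$burst_size,
            bc = ba, growth = p$noninduced_growth, cv = p$count_cv,
            vc = p$tube_vbr * ba
          )
          induc[[sid]] <- data.frame(
            sample_id = sid, treatment = tr, month = mo, plot = pl, assay
          )

          pk <- generate_trflp_replicates(
            comm_p, taxon_sizes,
            total_fluorescence = p$total_fluorescence,
            n_reps = p$trflp_reps, size_jitter_sd = p$size_jitter_sd,
            dropout = p$dropout, height_cv = p$height_cv
          )
          peaks[[sid]] <- data.frame(sample_id = sid, pk)

          edaph[[sid]] <- data.frame(
            sample_id = sid, treatment = tr, month = mo, plot = pl,
            moisture = pmax(2, 8 + 5 * oc + stats::rnorm(1, 0, 1)),
            organic_c = pmax(0.05, oc * rlnorm_cv(1, 0.05)),
            total_n = pmax(0.005, oc / 12 * rlnorm_cv(1, 0.05)),
            c_n = pmax(1, 10 + oc + stats::rnorm(1, 0, 0.5)),
            p = pmax(1, 30 + 5 * oc + stats::rnorm(1, 0, 3)),
            ph = pmin(8.5, pmax(4, 6.5 - 0.2 * oc + stats::rnorm(1, 0, 0.15)))
          )
        }
      }
    }

    # free and induced assemblages share a derived seed: the prophage pool
    # is hosted by the same community, so both draw the same treatment cores,
    # and the coupled flip streams make turnover differences directly
    # comparable between the two assemblages
    band_seed <- sample.int(2^31 - 2, 1)
    bands_free <- generate_band_profiles(
      p$treatments, p$months, pool_size = p$band_pool_size,
      core_richness = p$band_core_richness,
      core_divergence = p$band_core_divergence,
      turnover = p$band_turnover_free, seed = band_seed
    )
    bands_induced <- generate_band_profiles(
      p$treatments, p$months, pool_size = p$band_pool_size,
      core_richness = p$band_core_richness,
      core_divergence = p$band_core_divergence,
      turnover = p$band_turnover_induced, seed = band_seed
    )

    structure(list(
      enumeration = validate_study_table(do.call(rbind, enum), "enumeration"),
      induction = validate_study_table(do.call(rbind, induc), "induction"),
      peaks = validate_study_table(do.call(rbind, peaks), "peaks"),
      bands_free = validate_study_table(bands_free, "bands"),
      bands_induced = validate_study_table(bands_induced, "bands"),
      edaphics = validate_study_table(do.call(rbind, edaph), "edaphics"),
      truth = list(
        communities = truth_comm,
        taxon_sizes = taxon_sizes,
        lysogen_fraction = stats::setNames(p$lysogen_fraction, p$treatments),
        burst_size = p$burst_size
      ),
      params = p,
      seed = seed
    ), class = "synthetic_study")
  })
}
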