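---
title: "Methods: induction assays, community fingerprints, and ordination in soilvir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: induction assays, community fingerprints, and ordination in soilvir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilvir)
```

soilvir implements the computational chain of a seasonal soil viral-ecology
field study: quantification of mitomycin-C (mitC) prophage-induction assays,
T-RFLP community profiling with replicate consensus, genetic-fingerprint
similarity analysis, and the statistics linking microbial abundances to soil
edaphic variables. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-study generator
does and does not emulate.

## Prophage induction assays

A mitC induction assay produces four epifluorescence counts per soil sample:
viral and bacterial abundance in an untreated control tube (Vc, Bc) and in a
mitC-treated tube (Vm, Bm), all per gram of dry soil after an overnight
incubation. From these the package computes:

* **Burst size** BZ = (Vm − Vc) / (Bc − Bm): viruses released per lysed
  cell. Undefined when Vm ≤ Vc (`no_induction`) or Bm ≥ Bc
  (`growth_dominated`); defined values below 1 are flagged `low_burst`
  rather than discarded — a burst size under one virus per lysed cell is
  the classic sign that growth of non-induced cells during the incubation
  contaminated the bacterial delta.
* **Inducible fraction, calculated convention**
  IF = 100·[(Vm − Vc)/BZ]/Bc. Substituting BZ shows this is algebraically
  100·(Bc − Bm)/Bc, the fraction of control cells lysed; the identity is
  tested to 1e-12 relative tolerance.
* **Inducible fraction, assumed convention** IF20 =
  100·[(Vm − Vc)/20]/Bc, with the burst size fixed at 20 viruses per lysed
  cell (configurable).
* **Percent increase** 100·(Vm − Vc)/Vc, a burst-size-free qualitative
  induction measure.

Two conventions were genuinely open and are resolved as follows. The IF
denominator is the post-incubation control count Bc — the only control
bacterial count the assay produces; callers holding a separate pre-incubation
baseline can substitute it by constructing the assay table themselves.
Negative statistics (failed inductions) are reported with flags, never
clipped, because they carry the quality-control signal. Group summaries
report mean and sample SD across plot replicates; single-plot groups (an
unreplicated forest site is part of the default design) report the value
with SD absent.

## T-RFLP profiling

Replicate PCR profiles are reduced to one community vector per sample in a
fixed stage order: **align** replicate peaks by size (greedy, running-mean
anchored, tolerance 0.5 nt), **filter** to peaks present exactly once in
every replicate, **normalise** total fluorescence reiteratively — scale every
profile to the minimum replicate total, delete peaks under the relative
detection threshold (0.1% of the profile total), and repeat until a full
pass deletes nothing — then **remove** any remaining sub-threshold peaks,
re-enforce reproducibility, average size and height to a **consensus**
profile, **bin** consensus peaks across samples (greedy left-to-right, new
bin when a peak is more than 0.5 nt from the running bin mean), and compute
Shannon diversity H = −Σ p·ln p per sample row.

Numerical choices: the 0.1% rule uses a strict inequality ("less than"), so
a peak at exactly 0.1% survives; peak *height*, not area, is the abundance
proxy; binning ties (a peak exactly at tolerance) go to the earlier,
smaller-size bin, which together with pre-sorting makes the pipeline
invariant to input row order. Whether the detection threshold applies before
or after the reproducibility filter is not dictated by the field convention;
here the reproducibility filter runs first and the threshold doubles as the
deletion rule inside the reiterative normalisation, which is self-consistent
and keeps the normalisation convergent (the retained peak count strictly
decreases on every non-final pass). Both tolerances and the threshold are
arguments, not constants.

## Fingerprint similarity, clustering, and ordination

Band profiles (one per month × site label) are matched into a common column
space by greedy clustering of pooled positions with a tolerance
proportional to fragment size (default 2%, because gel mobility error grows
with fragment length; an absolute-bp mode exists). Pairwise similarity is
Dice's binary coefficient x = 100·2a/(2a + b + c); dissimilarity is the
involution y = 100 − x. The summary statistic is the mean of the strictly
upper triangle, reported with the most dissimilar pair.

Dendrograms use classic UPGMA (unweighted average linkage). Merge heights
are recorded as the merging distance itself — the cophenetic convention —
not half of it, so `cophenetic()` on the tree returns the average-linkage
merge distances and Newick branch lengths are unambiguous (a two-leaf tree
merged at height 3 serialises as `(A:3,B:3);`). Labels are sorted
lexicographically before clustering so distance ties break
deterministically. Band calling from densitometric traces treats local
maxima at ≥5% of the maximum trace intensity as bands and maxima between 2%
and 5% as "uncertain", excluded by default — a prominence-based reading of
the minimum-profiling/grey-zone screening convention, whose exact commercial
semantics are proprietary.

Ordination is Kruskal nonmetric MDS on the dissimilarity matrix. The
configuration starts from classical (Torgerson) scaling and alternates
pool-adjacent-violators monotone regression (primary treatment of ties:
within tied dissimilarity blocks the distances are pre-sorted, so they
impose no mutual constraint) with steepest descent on stress-1 =
sqrt(Σ(d − d̂)²/Σd²), using step-halving so the recorded stress trace is
non-increasing on every run. Four seeded random restarts supplement the
classical start and the lowest-stress solution is returned, making results
a pure function of the input and the seed. Identical profiles produce
exact-zero dissimilarities that break rank-based scaling; they are replaced
by half the smallest positive dissimilarity, with a warning. Convergence is
declared when an iteration improves stress by less than 1e-6 (or no
improving step of at least 2⁻³⁰ of the trial step exists).

## Statistics layer

**Spearman correlation** is the Pearson correlation of mid-ranks on
pairwise-complete data. Significance: t approximation for n ≥ 10; full
permutation enumeration for n ≤ 7; otherwise 10⁴ Monte-Carlo permutations
with the add-one convention. Summary tables mark the 0.05 / 0.01 / 0.001
tiers.

**Repeated-measures ANOVA** fits the additive model value ~ group + subject,
whose residual mean square is the group×subject interaction — exactly the
error term of the one-way within-subjects F — followed by Tukey HSD on the
same error term. Unbalanced designs are rejected with a pointer to listwise
completion rather than silently dropped.

**CCA** follows ter Braak: chi-square residuals Q = (P − rc′)/√(rc′) are
projected by weighted least squares onto centred, √r-weighted predictors
and the projection is eigen-decomposed. Eigenvalues are reported as
percentages of the total inertia Σ Q², the scaling-invariant quantity.
Site scores use Hill's scaling focused on inter-sample distances — the
weighted-orthonormal site vectors divided by √(1 − λ) per axis. Optional
down-weighting multiplies species rarer than max(frequency)/5 by
frequency/(max(frequency)/5). The Monte-Carlo permutation test permutes
environment rows against fixed sites, uses the sum of constrained
eigenvalues (trace) as its statistic, and reports the add-one p-value
(1 + #{perm ≥ obs})/(1 + n_perm), never exactly zero.

## The synthetic-study generator

`generate_study()` emulates the statistical structure the analysis assumes:
five treatments (two agricultural, two early-successional, one forest site),
six ordered months (May–November, August unsampled), triplicate plots
except a single plot for the forest site. Defaults, chosen once as
field-realistic values:

* bacterial abundance lognormal around 5×10⁸ cells g⁻¹, virus-to-bacteria
  ratio 5, count noise CV 0.3 (multiplicative lognormal, unit mean —
  microscopy counts are positive and span orders of magnitude);
* log-abundance rises with organic carbon (slope 0.5 per % C around
  treatment carbon contents 0.9–2.8%), and the month-to-month SD of log
  viral abundance scales with relative carbon content (0.4 at the mean), so
  seasonal variability and carbon are positively linked;
* lysogen fraction 0.02 per treatment (the assumed-burst inducible
  fractions this produces, roughly 0.4–13%, match the range such assays
  report), burst size 20, non-induced growth factor 1.2 acting equally on
  control and mitC tubes, control-tube viral baseline 0.1 of the cell
  count — which places the percent-increase statistic in the few-hundred
  percent range typical of positive induction events;
* 30-taxon communities drawn from Dirichlet(5) (concentrated enough that
  taxa stay above the 0.1% detection floor, so zero-noise runs round-trip
  exactly), fragment sizes as distinct even integers in 60–598 nt,
  0.15 nt size jitter, 2% peak dropout, 10% height noise;
* fingerprint band pool of 60 log-spaced positions (100–1500 bp), a global
  core of 25 bands perturbed per treatment at rate 0.12, and
  richness-preserving monthly turnover (losses at the turnover rate,
  gains at the balancing rate) of 0.05 for free extracellular and 0.15 for
  induced assemblages.

Two generator designs deserve note. First, turnover preserves expected band
richness; a naive per-position flip model drifts richness toward half the
pool, which *lowers* between-treatment dissimilarity as turnover rises and
confounds the free-vs-induced comparison. Second, the free and induced
assemblages of one study share a derived seed: both draw the same treatment
cores (the prophage pool is hosted by the same community), and turnover
decisions compare one fixed uniform stream against the two rates, so the
induced change set nests the free one. Under these defaults the average
dissimilarities land near 29 (free) and 44 (induced), the regime gel
fingerprint studies of such assemblages report.

The generator does **not** emulate: spatial structure within plots,
phage–host infection dynamics, adsorption/hydrology, gel-image artefacts
(co-migration of unrelated fragments, lane warping), PCR primer bias, or
pseudo-T-RFs. Passing tests therefore demonstrate that the analysis chain
recovers known structure from data with the assumed noise anatomy — not
that real gels or chromatograms satisfy those assumptions.

## Problem sizes and determinism

The test suite exercises the full study design (78 samples, 30 taxa, 30
fingerprint labels), 10⁴-assay identity checks, 50-seed Monte-Carlo checks
of the growth pathology and of the free/induced dissimilarity ordering,
20-seed NMDS separation checks, and a 500-dataset calibration of the CCA
permutation p-value at 199 permutations each — sizes at which every
stochastic check is stable across seeds while the whole suite stays fast.
Every stochastic function takes an explicit seed and restores the caller's
RNG state; the command-line stages write a JSON sidecar with the seed and a
hash of the resolved configuration, and rerunning any stage with the same
seed reproduces outputs byte-for-byte.

## Known limitations

* The calculated-IF convention cannot exceed the information in the
  bacterial counts; when growth dominates (Bm ≥ Bc) it is undefined and
  only the assumed-burst and percent-increase statistics remain.
* NMDS minimises a non-convex stress; with few restarts distinct label
  orders can settle in different local minima. Raising `n_restarts` buys
  stability at linear cost.
* Greedy left-to-right binning is deterministic and order-invariant but not
  globally optimal; pathological peak spacings straddling the tolerance can
  split differently than a clustering that sees all peaks at once.
* The CCA permutation test permutes rows freely and is exact only under
  exchangeability; with strong temporal autocorrelation a restricted
  permutation scheme would be needed.
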