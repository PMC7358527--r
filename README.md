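# soilvir

Analysis pipelines for seasonal soil viral-ecology field studies.

Soils host enormous viral communities whose interactions with bacteria —
lytic infection versus dormant lysogeny — shape nutrient cycling and
microbial community structure, yet the field-scale data such studies
produce are heterogeneous: epifluorescence counts from induction assays,
T-RFLP electropherogram peak tables, gel fingerprint band lists, and soil
chemistry tables. soilvir turns each of these into the quantities the
literature reports, with a seeded synthetic-study generator that lets every
stage be validated against known ground truth. It is written for microbial
ecologists processing enumeration/induction/fingerprint data and for
methodologists who want a fully reproducible reference implementation of
this analysis chain.

## What it computes

**Prophage induction.** From the four counts of a mitomycin-C induction
assay (control/treated viral counts Vc, Vm and bacterial counts Bc, Bm):

- burst size `BZ = (Vm − Vc) / (Bc − Bm)`, with degenerate cases flagged
  (`no_induction`, `growth_dominated`, `low_burst` for BZ < 1);
- inducible fraction with calculated burst size,
  `IF = 100·[(Vm − Vc)/BZ]/Bc ≡ 100·(Bc − Bm)/Bc`;
- inducible fraction with an assumed burst size of 20,
  `IF20 = 100·[(Vm − Vc)/20]/Bc`;
- percent increase in viral abundance, `100·(Vm − Vc)/Vc`;
- virus-to-bacteria ratio `VBR = VA/BA`, and treatment × month summaries.

**T-RFLP profiling.** Replicate alignment → reproducibility filter →
reiterative total-fluorescence normalisation with a 0.1% detection
threshold → consensus → 0.5-nt cross-sample binning → relative-abundance
matrix and Shannon diversity `H = −Σ p ln p`.

**Fingerprint analysis.** Band calling and matching, Dice similarity
`x = 100·2a/(2a+b+c)`, dissimilarity `y = 100 − x`, average/maximum
dissimilarity, UPGMA dendrograms (Newick export), and Kruskal nonmetric
MDS with stress-1.

**Statistics.** Spearman rank correlations (exact small-sample p-values),
one-way repeated-measures ANOVA with Tukey HSD, seasonal
variability-versus-carbon analysis, and canonical correspondence analysis
(Hill's scaling, optional rare-species down-weighting) with a Monte-Carlo
permutation test.

## Worked example

```r
library(soilvir)

# one induction assay: 5e7 extra viruses, 5e6 cells lysed
assay <- induction_assay(v_control = 1.0e8, v_mitc = 1.5e8,
                         b_control = 5.0e7, b_mitc = 4.5e7)
induction_stats(assay, assumed_bz = 20)
#>   delta_v bz_calc if_calc if_assumed pct_increase no_induction growth_dominated low_burst
#> 1   5e+07      10      10          5           50        FALSE            FALSE     FALSE

# a full synthetic study: 5 treatments x 6 months, triplicate plots
study <- generate_study(generator_params(), seed = 1)
res <- trflp_pipeline(study$peaks)
res$qc$unique_trfs              # 30
round(res$qc$mean_peaks_per_profile, 1)  # 27.8
round(range(res$diversity), 2)  # 3.15 3.38

fp <- fingerprint_pipeline(study$bands_free, seed = 1)
round(fp$avg_dissimilarity$mean, 2)  # 28.66
round(fp$mds$stress, 3)              # 0.135
```

The burst size of 10 means ten viruses were released per lysed cell; the
calculated IF of 10% is the lysed fraction of control cells, while IF20
(5%) rescales the viral delta by the assumed burst size of 20. In the
synthetic study, all 30 community taxa are recovered as unique terminal
restriction fragments (27.8 reproducible peaks per profile after the
filters), Shannon diversity sits in the 3.1–3.4 range, and the free viral
assemblages ordinate at stress 0.135 — an acceptable 2-D representation.

A command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/soilvir simulate --seed 7 --out data/
Rscript inst/scripts/soilvir trflp --in data/peaks.csv --out data/ --bin-tol 0.5
```

Every stage writes a JSON sidecar with the seed and configuration hash;
rerunning with the same seed reproduces outputs byte-for-byte.

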