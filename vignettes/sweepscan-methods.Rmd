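---
title: "sweepscan: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sweepscan: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# What the package computes

`sweepscan` detects selective sweeps that differentiate two populations of a
diploid species — typically a trait-selected "object" group contrasted with a
"reference" group (the motivating use case is fat-tailed versus thin-tailed
sheep breeds) — from a joint multi-sample VCF. Three complementary signals
are scanned, their outlier regions are mapped to genes, and the three-method
gene intersection is tested for term over-representation:

1. **Windowed FST / π.** 50 kb windows every 25 kb. Per window, the
   Weir–Cockerham (1984) two-population FST is computed by summing the
   per-site variance components *a* (among populations), *b* (among
   individuals within populations) and *c* (within individuals) and taking
   `sum(a) / sum(a+b+c)` — the "weighted" estimator of the common VCF
   toolchains. Nucleotide diversity per group is the per-site unbiased
   heterozygosity `2 p (1 − p) n/(n − 1)` summed over SNPs and divided by
   the full window span, so unsequenced positions count as invariant. FST is
   Z-standardised genome-wide (sample sd, ddof 1) and the diversity contrast
   is `log2(π_ref / π_obj)`, so positive values mean diversity loss in the
   object group. Joint outliers are windows extreme in both metrics;
   overlapping flagged windows merge into maximal regions.
2. **Composite-likelihood sweep scan (XP-CLR style).** At each grid
   position, nearby SNPs (within a genetic-distance window, nearest first,
   capped) are scored under a neutral model — the object-population allele
   frequency around the reference frequency `p1` follows a normal with
   variance `ω p1(1 − p1)`, truncated to (0,1) with the clipped mass on
   atoms at 0 and 1 — against a hitchhiking model in which a SNP at genetic
   distance `r` escapes the sweep with probability `c = 1 − exp(−r/s)` and
   is otherwise dragged towards fixation of whichever allele rode the
   beneficial background (probability `p1` for the derived allele). The
   score is twice the weighted composite log-likelihood ratio maximised
   over a selection grid; correlated SNPs (genotype r² above 0.95) share
   down-weighted cluster weight. The drift scale ω is a method-of-moments
   genome-wide estimate, `mean[(p2 − p1)² / (p1(1 − p1))]`.
3. **ROH islands.** A PLINK-style window scan calls per-individual runs of
   homozygosity; the per-SNP percentage of object-group individuals covered
   by a run is the occurrence track, and maximal runs of SNPs strictly above
   the threshold (20% by default; 30% available, as both values appear in
   the source literature) are ROH islands.

Genes are mapped to regions by any ≥1 bp overlap on half-open intervals
(flank configurable, 0 by default). The consensus is the strict triple
intersection. Enrichment is the exact hypergeometric upper tail
`P[X ≥ k]` with Benjamini–Hochberg adjustment across terms; this replaces
service-based GO tools whose backgrounds and modified scores are not
reproducible offline, and is labelled as such in the output.

# The synthetic world

Because the motivating study's 555-genome cohort is not reproducible at desk
scale, every stage is exercised on a forward Wright–Fisher simulation
(`simulate_two_pop()`): an ancestral pool of `2 Ne` haplotypes is seeded with
`n_sites` segregating sites whose derived-allele counts follow the neutral
SFS (`P(count = i) ∝ 1/i`) at linkage equilibrium, the pool is duplicated
into object and reference populations, and each drifts independently for
`split_generations` generations with Poisson-recombination gametes and
random union of gametes. No new mutations arise after the split, so both
populations segregate one common SNP panel, as in a joint-called VCF. Hard
sweeps start from a single copy in the object population immediately after
the split, with fitness 1, 1+s, 1+2s, and are conditioned on fixation by
restarting the object population from the split state whenever the allele is
lost (a generation cap turns pathologically weak sweeps into an error).

## Why the desk-scale defaults look the way they do

The defaults (50 diploids sampled per group from `Ne = 1000` simulated
diploids, 2 Mb, 2,000 sites, 300 generations, recombination 2e-7 Morgans/bp,
s = 0.1) were chosen by an explicit signal-geometry calculation, not by
fitting to test outcomes:

* The toy sequence stands in for a whole chromosome. With a literal
  1 cM/Mb map the 2 Mb sequence is 2 cM long while an s = 0.1 sweep
  distorts roughly `s / ln(2 Ne s)` Morgans around the site — the entire
  sequence hitchhikes to fixation and nothing is localisable. At 2e-7
  Morgans/bp the map is ~0.4 Morgans and the footprint
  `s / (ln(2 Ne s) · rate)` is ≈ 90 kb: interior, comparable to the 50 kb
  windows, and recoverable by all three methods.
* Drift must be visible but not saturating. Simulating the population at
  the sample size (50 diploids) over 300 generations is 3 coalescent units:
  ~95% of seeded diversity is lost and genome-wide FST reaches ~0.95,
  swamping any sweep. At `Ne = 1000` the same 300 generations give ~0.15
  units — genome-wide FST ≈ 0.15–0.2, the regime of real between-breed
  contrasts.
* The ROH "test" preset follows the same geometry: at the post-QC density
  of ~0.33 SNP/kb, 15-SNP windows span ~45 kb; the 100 kb minimum length
  sits below the ≈ 95 kb expected sweep ROH but above the background ROH
  produced by recent coalescence (needing common ancestry within ~25
  generations, a ~1% event per individual). The "plink" preset keeps the
  published full-scale values (50-SNP windows, > 0.5 Mb).

What the generator deliberately does **not** emulate: new mutation after
the split, migration, bottlenecks or growth, soft sweeps, background
selection, variable recombination, genotyping error, and allele-frequency
ascertainment. A green planted-sweep test therefore establishes that the
statistics recover a clean hard sweep in a clean split — not that they are
calibrated for any particular real demography.

# Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| window / step | 50,000 / 25,000 | bp | published window strategy |
| outlier mode | quantile, q = 0.05 | – | robust at any data scale; the published absolute cuts (z > 1.58, ratio 0.24) are data-set-specific and available as `mode = "absolute"` |
| XP-CLR grid spacing | 2,000 (5,000 in test preset) | bp | the published flag string uses 2000 where the prose says 1 kb; the conflict is preserved as configuration with the flag string as default |
| window genetic span | 0.005 | Morgans | published `-w1` value, read as a radius around the grid point |
| max SNPs / window | 200 (100 in test preset) | – | published cap |
| r² threshold | 0.95 | – | published down-weighting rule |
| s grid | 12 log-spaced, 1e-5…0.5 | – | an effectively-neutral model is always also evaluated, so scores are ≥ 0 and `s_hat = 0` denotes a neutral fit |
| top fraction | 0.01 | – | published top-1% rule |
| ROH length | > 0.5 Mb ("plink") / > 0.1 Mb ("test") | bp | published threshold; desk scaling above |
| island threshold | 20 (30 optional) | % | both values appear in the source; 20 (Methods) is the default |
| enrichment α | 0.05 | – | raw-p rule mirroring the published reporting; BH values also emitted |

# Numerical choices

* **Frequency integration.** The truncated-normal density is discretised on
  512 midpoint cells with *exact* cell masses (normal CDF differences), so
  mass + atoms = 1 to machine precision for any (p1, ω) and the density
  normalisation criterion is met by construction rather than by quadrature
  accuracy. ω = 0 degenerates to a point mass at p1, which makes the
  "identical populations give score exactly 0" identity hold in floating
  point.
* **Clamping.** The plug-in reference frequency is clamped to
  `[1/(2 n_ref + 2), 1 − 1/(2 n_ref + 2)]` to avoid zero-variance neutral
  densities at sites monomorphic in the reference sample.
* **Likelihood floors.** Site likelihoods are floored at 1e-300 before
  logging so fully incompatible sites cannot produce NaN scores.
* **Degenerate distances.** A SNP exactly at the grid point gets half a
  base pair of genetic distance so the neutral limit (`c → 1`) stays exact.
* **Ties.** Quantile-based flagging (top-q windows, top-1% scores) uses the
  k-th largest value as an inclusive cutoff, so ties at the boundary are
  all included and flagged sets are monotone in q.
* **Undefined values.** Windows with no usable SNP have `NaN` FST; windows
  where either group's π is 0 have an undefined log2 ratio; both are
  excluded from transforms and outlier calling (and logged). At the default
  synthetic geometry this touches at most a window or two per run.
* **Coordinates.** Internal intervals are 0-based half-open; VCF and TSV
  outputs are 1-based (TSV start/end inclusive), BED is 0-based half-open.
  ROH segments span first to last run SNP.

# Design decisions on genuinely open points

* The source literature never defines the π-ratio subscripts, and its
  "< 0.24" direction contradicts selecting diversity-depressed windows in
  the fat-tailed group. The ratio here is oriented `π_ref / π_obj` (so
  sweeps in the object group give large positive log2 values), and both the
  direction and the threshold are configuration; the published constants
  are available as the absolute preset.
* Whether Z-standardisation was genome-wide or per chromosome is unstated;
  genome-wide is used.
* The QD/MQ/FS filter and the call-rate/MAF/depth filter commute (both are
  per-site predicates on immutable statistics — a property the test suite
  checks), so their unstated order is immaterial; the pipeline runs
  variant-quality first.
* "Mean maximum depth below 3 or above 30" is read as the per-site mean
  depth across samples, the only depth statistic computable from a standard
  VCF that matches a 3–30 band.
* Window-to-gene assignment uses window overlap (not per-SNP overlap),
  with a configurable flank, since the source is ambiguous.
* The original XP-CLR binary's SNP grouping is unspecified; weights here
  use greedy position-ordered clustering against the cluster head on
  object-group genotypes. Bit-compatibility with the original executable is
  explicitly a non-goal: validity is established by the property suite
  (nested-model zero, non-negativity, density normalisation, planted-sweep
  localisation).
* Alleles are not polarised to an ancestral state; alternate-allele
  frequencies are used throughout.
* Run configs are TOML; since no TOML parser is available in the supported
  dependency set, a documented subset reader (`read_toml_lite()`) handles
  sections, scalars and flat arrays.

# Known limitations

* The composite-likelihood scan's selection-strength estimate `s_hat` is a
  grid argmax, useful for ranking, not for inference about s.
* ROH calling is the PLINK-style heuristic, not an HMM; inbreeding
  coefficients (F_ROH) are out of scope.
* Enrichment ignores term-graph structure (no ancestor propagation) and
  treats the annotation's gene universe as the background.
* The simulator's exchangeable-individual sampling means the 50-diploid
  sample is drawn as the first 50 of the simulated population; there is no
  family structure or unequal sampling.
* Haplotype-based statistics (iHS, XP-EHH), per-site FST output and
  graphical output are out of scope.
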