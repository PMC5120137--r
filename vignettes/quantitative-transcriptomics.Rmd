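---
title: "Quantitative transcriptomics with internal RNA standards: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative transcriptomics with internal RNA standards: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txcell)
```

## The measurement model

`txcell` analyses bacterial transcriptomes on an absolute,
transcripts-per-cell scale. The measurement chain it models is: a culture
sample of *N* cells is collected on a filter; a cocktail of internal RNA
standards — in-vitro transcripts of known sequence, length and copy number
*S~j~* — is added before extraction; the library is sequenced to *R* reads;
and a gene observed at *r~g~* reads is converted to molecules through the
standards' recovery. Two estimators summarise that recovery:

* a log--log OLS regression of reads on copies added, used as **quality
  control**: slope near 1 and r² near 1 mean recovery was log-linear over
  the spiked range, and standards falling off the line indicate handling or
  synthesis problems;
* the pooled ratio **conversion factor** `k = sum(reads) / sum(copies)`
  over retained standards, used for the actual conversion
  `copies_g = r_g / k` and `a_g = r_g / (k N)` transcripts per cell.

The pooled ratio rather than the regression line is used for conversion
because it is robust to per-standard counting noise, exactly invertible
against the package's own library simulator, and an unbiased estimator of
reads-per-molecule under multinomial sampling (a property the test suite
checks over 100 simulated libraries). The regression intercept is left
free: forcing it through the origin would conflate slope and scale errors
and would blunt the regression's diagnostic value.

Two conversion modes are provided. In **per-copy** mode (default) a
feature's read weight is its molecule count — appropriate when standards
and transcripts are sequenced end-to-end as whole molecules of known
number. In **length-weighted** mode weights carry an extra factor of
feature length, emulating fragment sequencing; it must be paired with
length-weighted calibration (`fit_recovery(..., mode =
"length-weighted")`), and the mode travels inside the `calibration_fit` so
mismatched conversions are a hard error.

## Flagging badly recovered standards

Spike-in experiments routinely lose a few standards to synthesis or
pooling problems; the analysis must find them rather than trust them. A
standard is flagged when its per-copy recovery ratio deviates from the
geometric mean ratio of the others by more than a threshold (default
2-fold, strict inequality — a standard at exactly 2-fold is kept).

The reference mean is computed by **greedy peeling**: the single worst
deviator is removed, the geometric mean recomputed, and the rule
re-applied until no retained standard exceeds the threshold; every standard
is then re-evaluated against the final reference. A one-pass version of
this rule is fragile by arithmetic, not just in unlucky samples: with 3 of
14 standards corrupted 20-fold low, the raw geometric mean is dragged down
by 20^(3/14) ≈ 1.9-fold, leaving every clean standard within 5% of the
threshold, so ordinary counting noise can flag all of them at once and
empty the reference set. Peeling makes the flagged set a stable fixed point
of the same rule. Standards with zero reads cannot enter the log
regression (they are dropped from it with a warning) but keep a ratio of
0 and are therefore always flagged. Flagged standards are reported;
exclusion is an explicit caller decision (`fit_recovery(..., exclude =
...)`), and re-inclusion restores the original fit exactly.

## The synthetic-data generator

The generator produces data with the statistical structure the analysis
assumes, so parameter recovery can be tested end to end.

* **Genome**: 1,377 genes by default, mean length 944 nt (a ~1.3 Mbp
  streamlined genome); lengths are `50 + Gamma(shape = 4)`, a bounded
  positive distribution with the stated mean.
* **Expression**: per-gene abundances are lognormal in log10 space and
  rescaled to sum exactly to the cell's total mRNA content. The default
  spread `sigma_log10 = 0.70` was calibrated by search so the
  log10(max/min) span across 1,377 genes averages ~4.6 orders of
  magnitude. Phase presets for the total: 1,859 (exponential), 720
  (late-exponential), 387 (stationary), 17 (deep stationary) transcripts
  cell⁻¹.
* **Standards**: 14 spike-ins in 4 groups, copies log-spaced over 4 orders
  of magnitude (10⁸–10¹² molecules per sample), lengths 500–1,500 nt. The
  group count and spiked range match the experimental design the package
  emulates; the specific copy numbers and lengths are package choices.
  "Badly recovered" standards are modelled as fixed multiplicative
  recovery biases (e.g. 0.05× for a 20-fold loss).
* **Libraries**: read counts are one multinomial draw of exactly
  `library_size` reads over genes plus standards, with weights as in the
  chosen mode. Presets use 3×10⁵–3×10⁶ reads per library and 3×10⁹ cells
  collected (about a litre of culture at 3×10⁶ cells ml⁻¹); with the
  default standards this puts ~25% of reads in spike-ins for an
  exponential-phase sample, rising in stationary phase as the mRNA pool
  shrinks — the expected behaviour when a fixed standard cocktail meets a
  variable transcript pool.
* **Growth**: closed-form logistic trajectories with exponential rates in
  0.06–0.09 h⁻¹ by regime, carrying capacities of 3×10⁶ (methanol +
  nutrients), 1.4×10⁷ (with vitamins) and 5.4×10⁵ cells ml⁻¹ (DOM in
  UV-oxidized medium), inoculum 10³ cells ml⁻¹; replicate noise is
  multiplicative lognormal with a CV parameter.
* **Methanol**: concentrations follow the carbon budget exactly,
  `C(t) = c0 − ΔN(t)·Q/(BGE·M_C·10⁶)` µM with cumulative production
  ΔN(t); exhaustion clips at zero with a warning rather than an error,
  since real cultures can run the substrate out.

Seeds are explicit arguments everywhere; nothing depends on global RNG
state, and a fixed seed reproduces every table byte for byte.

**What the generator does not emulate.** Per-gene counts are exactly
multinomial: there is no biological overdispersion beyond the planted
replicate CV, no length or GC bias in per-copy mode, no mapping error or
multi-mapping ambiguity, and no rRNA carryover. Passing recovery tests
therefore demonstrates that the estimators are correct under the stated
sampling model, not that real libraries meet that model; with real data
the recovery regression and its outlier flags are the diagnostic that the
model approximately holds.

## Growth phases and the carbon budget

Interval growth rates µ = ln(N₂/N₁)/Δt are classified against the curve's
maximum rate: exponential at ≥ 0.8 µ_max, late-exponential in
[0.2, 0.8) µ_max, stationary below 0.2 µ_max in magnitude, decline at
≤ −0.2 µ_max, with stationary stretches longer than 100 h relabelled deep
stationary and pre-exponential stationary points labelled lag. The 0.8/0.2
fractions and the 100 h cutoff are package choices — growth phases are
qualitative field terms, and these thresholds reproduce the qualitative
phase sequence of logistic batch curves; all three are arguments. The
generation-time relation is implemented as g = ln 2/µ (equivalently µ =
1.443/g — the 1.443 = 1/ln 2 factor connects doubling time and rate; a
formulation that multiplies the rate itself by 1.443 is dimensionally
inconsistent and is not used).

The yield model is linear: each µM of methanol consumed provides
M_C × 10⁶ fg of carbon per ml, of which a fraction BGE (default 0.22)
becomes biomass, at Q (default 10) fg C per cell. The molar mass constant
12.011 g mol⁻¹ counts only the single carbon of methanol. `simulate_drawdown`
and `theoretical_yield` are exact algebraic inverses, and the test suite
holds the round trip to 10⁻¹² relative error.

## Differential-abundance calling

The calling scheme is deliberately classical, matching how such data are
analysed in practice: per-gene one-way fixed-effects ANOVA across the four
regimes' late-exponential triplicates; Benjamini–Hochberg step-up
correction applied **across genes to the ANOVA p-values only** (pairwise
p-values stay unadjusted, gated behind the gene-level q < 0.05); pooled-SD
pairwise t tests (the common within-group variance over all four groups,
N − k degrees of freedom); and a call of + or − only when the pairwise p
is below α = 0.05 **and** the regime means differ by at least 2-fold.
ANOVA, BH and the pairwise tests are implemented in the package and are
cross-checked in the test suite against `stats::aov`, `stats::p.adjust`,
`stats::pairwise.t.test`, a brute-force step-up implementation and a
permutation oracle. Per-pair Holm adjustment is available via
`bh_adjust` on the pairwise matrix should a user want it, but the default
follows the plain p < 0.05 pairwise rule.

Zeros are kept as true zeros throughout quantification — no pseudocount —
because the absolute scale must stay unbiased; a pseudocount appears only
where a log transform needs one (clustering, below). Fold changes against
a zero denominator are reported as infinite with a warning, and 0/0 as
missing. The "similar across regimes" flag (`flag_similar_genes`) is the
complement of calling: a gene whose regime means all lie within 2-fold
(max pairwise |log2 FC| < 1) is flagged similar, with the ANOVA q reported
alongside but not gating the flag — similarity is a statement about effect
size, and tying it to a significance test would flag noisy genes as
"similar" merely for being untestable.

## Sample clustering

Distances are 1 − Pearson r between genome-wide profiles, agglomerated
with complete linkage (`stats::hclust`), whose merge heights are
guaranteed monotone. Because abundances span ~5 orders of magnitude, raw
Pearson correlation would be dominated by the handful of most abundant
genes; the default therefore clusters log10(x + pseudocount) with the
pseudocount set to half the smallest nonzero abundance — small enough not
to compress real signal, large enough to keep zeros finite. Raw-scale
clustering (`log_transform = FALSE`) is available, in which distances are
exactly invariant to per-sample affine rescaling. Samples are ordered
lexicographically by id before agglomeration so ties break
deterministically, and dendrograms export as Newick text.

## Numerical choices and degenerate inputs

* Expression rescaling holds Σa_g equal to the requested total to 10⁻⁹
  relative tolerance; `sigma_log10 = 0` is the exact flat profile.
* ANOVA on identical constants returns F = 0, p = 1; distinct constants
  with zero within-group variance return F = ∞, p = 0; a zero pooled
  variance with unequal means in a t test yields the smallest
  representable double rather than an exact zero, with a message.
* The outlier threshold comparison uses a 10⁻⁹ relative guard so that a
  standard at exactly the threshold fold is never flagged by floating-point
  noise.
* All-zero samples propagate as missing span with a warning rather than an
  error; all-zero standard sets are a calibration failure (hard error).
* Derived seeds in `simulate_dataset` and the acceptance script are folded
  below 2³¹ so integer seeds of any size are safe.

## Problem sizes

The test suite and the acceptance script run full-genome (1,377-gene)
single-library recoveries at 10⁶ reads, multi-seed calibration sweeps (25
seeds), 20-seed total-mRNA recoveries at four planted totals, a
10,000-gene null for ANOVA uniformity, 1,000 random vectors for the exact
BH check, and 20-seed cluster-nesting simulations at 200–300 genes; the
whole suite completes in well under a minute on one CPU. These sizes were
chosen to estimate each rate or error with comfortable Monte-Carlo margin
while keeping the default run fast.

## Known limitations

* The simulator's multinomial baseline understates replicate variance of
  real libraries; recovery tolerances would need widening for overdispersed
  data.
* Length-weighted mode models fragment counts as proportional to length ×
  copies, with no fragment-end or GC bias.
* The phase classifier labels from interval rates on replicate means; very
  sparse time series (the minimum is 3 points) classify coarsely.
* `fold_vs_others` uses the arithmetic mean of the other regimes' means,
  matching the reporting convention it reproduces; a geometric-mean variant
  would down-weight one dominant regime but would not match that
  convention.
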