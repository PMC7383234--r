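---
title: "Models and methods behind kv64pain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kv64pain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kv64pain)
```

kv64pain reimplements, as tested reusable code, the statistical chain of a
cohort study that linked a rare *KCNG4* (K~V~6.4) allele to reduced labor
pain: a rare-allele enrichment scan of a small case cohort against
population reference frequencies, quantitative sensory testing (QST) group
statistics, voltage-clamp curve fitting for the channel phenotype, and
single-cell qRT-PCR expression calling. No raw study data are distributed;
every analysis runs closed-loop on synthetic data whose generating models
are the ones the analyses assume, so parameter recovery can be verified
against known truth.

## Carrier enrichment against reference frequencies

Each SNP is summarized by its cohort counts (rare-allele count over
`2 * n_assessed` chromosomes, or carrier count over `n_assessed`
individuals) and a population reference frequency. Coverage is per-SNP:
exome panels do not assess every SNP in every individual, so each test uses
its own denominator. The deviation test is a two-tailed chi-square with the
Yates continuity correction, in one of two layouts:

* **goodness-of-fit** against expected counts `trials * ref_freq`, with
  `chi2 = sum((|O - E| - 0.5)^2 / E)` and the corrected deviation floored
  at zero when `|O - E| < 0.5` (otherwise tiny deviations would *add*
  signal);
* **2x2 contingency** against a reference cohort of known size, with the
  closed form `N (|ad - bc| - N/2)^2 / ((a+b)(c+d)(a+c)(b+d))`.

The combined discovery + replication carrier test defaults to the 2x2
layout with reference carriers rounded to whole individuals
(`round(0.0072 * 18878) = 136`); this is the only reading that reproduces
the published statistic of 4.779 for 4 carriers among 158 versus that
reference, so it is the default, with the goodness-of-fit and unrounded
variants exposed by argument (the unrounded 2x2 gives 4.784). Similarly,
the phrase "allele frequency of 0.0072 for heterozygote carriers" is read
as a **carrier** frequency, because `158 * 0.0072 = 1.14` matches the
published expectation of 1.1 carriers; both conventions are supported via
`ref_freq_kind`, and the genome-wide scan defaults to allele counts.

Raw p-values are adjusted two ways, Bonferroni and Benjamini-Hochberg
step-up FDR, both over the number of SNPs actually tested in the run — the
multiple-testing universe is a property of the data, not a constant.
Records with expected counts below 0.5 are still tested but flagged
`small_expected`: the original analysis itself tested an expectation of
0.7, and the chi-square approximation is known to be rough there (the
suite's calibration checks therefore only assert nominal type-I error for
expected counts of at least 5).

The filter cascade applies, in configurable order, the annotation stages of
the original analysis: a significance gate, a clear-cut protein-changing
consequence filter, an ion-channel gene-set filter, removal of SNPs whose
rare allele is common in mammalian orthologs, and removal of flagged
calling/alignment artifacts. The cascade report records `n_in`/`n_out`
and the removed identifiers at every stage, so the pipeline's attrition is
auditable. Ranked outputs sort stably by `(raw p, snp_id)`.

## The cohort generator

`gen_cohort()` is the null and alternative model in code: reference
frequencies drawn log-uniformly (a heavy-tailed spectrum resembling site
frequency spectra; a plain-uniform option exists for calibration studies at
common frequencies), carrier counts binomial at the reference frequency,
allele counts multinomial under Hardy-Weinberg, per-SNP coverage thinned by
a dropout probability, and enrichment simulated by multiplying selected
SNPs' frequencies (capped at 1). Every generator in the package takes an
explicit seed, restores the caller's RNG state, and returns its ground
truth, so downstream tests are generate-analyze-compare loops.

Two simulation regimes are fixed in the test suite and acceptance script:

* **Calibration**: 2,000 SNPs, allele mode, frequencies uniform on
  0.05-0.45 in 100 individuals, so every expected count is at least 5.
  Empirical type-I error at alpha = 0.05 lands near 0.04-0.05 — the Yates
  correction is mildly conservative, which is the expected behavior.
* **Power**: one SNP at the study's reference carrier frequency (0.0072)
  enriched x6 in 100 individuals, scanned among 50 null SNPs; BH q < 0.05
  is reached in roughly 55-65% of replicates (the condition sits on a knife
  edge: an observed count of 4 carriers is just significant after BH at
  this scan size, so power is dominated by the binomial tail above 3). This mirrors the study's
  marginal discovery-cohort power (3 observed carriers against 0.7
  expected), and is the reason a replication cohort was needed.

What these simulations do **not** model: linkage disequilibrium between
SNPs, population stratification, sequencing error, or reference-panel
mismatch. Passing them shows the statistics are correctly calibrated under
the stated sampling model, not that the original study design was immune
to those confounders.

## QST group statistics

Two-group comparisons run from `(n, mean, SD)` summaries — the form in
which published tables survive — or from raw vectors. The pooled Student
test uses `df = n1 + n2 - 2`; Welch uses the Welch-Satterthwaite df; the
Mann-Whitney U uses the exact distribution for combined n of 20 or fewer
without ties, and the tie-corrected normal approximation otherwise.
Family-wise correction is Sidak, `1 - (1 - p)^m`, with `m` the size of the
comparison's assessment domain (detection/pain thresholds, tolerance,
questionnaires); family membership is explicit configuration. A family
size of 6 for the thresholds block reproduces the published adjusted
values (0.018 to 0.103, 0.00002 to 0.00012).

Welch is the package default (robust to unequal variances); the published
table does not say which test produced each row. Two rows deserve note.
For the cuff-pressure row, the pooled test gives p = 2.08e-5, which rounds
to the printed 0.00002, and 6 x 0.00002 matches the printed adjusted
0.00012; Welch gives 1.49e-5, which does not round to the printed value —
so that row was evidently a pooled test. For the heat-pain row neither
summary-statistic t reproduces the printed 0.018 (both give ~0.024),
indicating a raw-data or rank-based test we cannot reconstruct from
summaries; the package reports its own computed values and leaves the
discrepancy documented rather than guessed.

## Electrophysiology fits

All currents are handled in pA, voltages in mV, time in ms (nA inputs are
converted on construction). The analysis chain is:

1. **Leak subtraction.** Ohmic leak `I = g (V - V_rev)` is fitted by least
   squares to steady-state currents of sweeps inside a leak window where
   the channels are closed (at least two sweeps required) and subtracted
   from every sample, using the per-sample command voltage.
2. **Activation.** Tail amplitudes are the peak absolute deviation from
   the late-tail baseline within the first 10 ms of the tail (both windows
   configurable — the source protocol says only "normalized tail
   currents"), normalized to the maximum, and fitted with the Boltzmann
   `y = t / (1 + exp((V50 - E)/k))` by Levenberg-Marquardt. Default
   initialization: `t` at the maximum, `V50` at the interpolated half-max
   crossing, `k = (V90 - V10)/4.39`. The top is free by default and can be
   fixed to 1 for pre-normalized data. After fitting, `y(V50) = t/2` holds
   by construction and the midpoint is checked to lie within the sampled
   span plus one span.
3. **Steady-state inactivation.** Availability points are fitted with a
   single or a sum-of-two Boltzmann; the double fit bounds the fraction F
   in [0, 1], keeps slopes positive, multistarts from jittered seeded
   initializations, and orders components so the more depolarized midpoint
   is component 1 (ties broken by larger F). Fits whose midpoints are
   within 2 mV, or whose F lands within 0.05 of a boundary, are flagged
   degenerate rather than silently reported. The raw `nls.lm` optimizer is
   used because a parameter converging onto a bound (F at 0 or 1) makes
   the wrapped-`nls` Jacobian singular.
4. **Toxin subtraction.** The stromatoxin-sensitive current is the exact
   pointwise difference pre minus post; the generator's paired series are
   calibrated so the sensitive fraction of steady-state current peaks at
   the +20 mV step at 52.7%, the study's condition.
5. **Recovery.** `y(dt) = 1 - A exp(-dt/tau)` fitted by least squares;
   the alternative anchored form `y0 + (1 - y0)(1 - exp(-dt/tau))` is a
   reparameterization of the same family (the source says only "single
   exponential").
6. **Excitability.** Action-potential thresholds from a 0-1 nA/1 s ramp
   (injected current at the first spike) and a +10 pA/50 ms step family
   (smallest spiking step). The spike criterion — dV/dt of at least
   10 mV/ms followed by overshoot above 0 mV within 5 ms — is this
   package's choice; the source states none. Capsaicin responders are
   cells whose mean inward deflection during the 5 s application window
   exceeds 5 baseline SDs.

The synthetic current-clamp cell is a leaky integrate-and-fire (LIF)
neuron (rest -60 mV, threshold -40 mV, 100 MOhm, tau 10 ms), chosen
because its ramp and step thresholds have closed forms to test against:
rheobase `(V_th - V_rest)/R = 200 pA`, and a ramp threshold of rheobase
plus `a * tau` for slow ramps. It is a detection-oracle stand-in, not a
biophysical K~V~2.1 model; the channel's effect on real neuronal
excitability is outside simulation scope. Note that a finite-duration step
at exactly rheobase only asymptotes toward threshold, so the detected step
threshold sits in the first grid step *above* the analytic value — the
tests assert exactly that bracket.

### Identifiability of the double Boltzmann

A sum of two Boltzmanns with midpoints 30 mV apart and slopes of 10-12 mV
is nearly one broad sigmoid; with 16 voltages and 0.02 normalized noise
the two midpoints and the fraction are weakly identified. Under seeded
simulation at that regime the packaged fitter's median midpoint errors are
5-7 mV and the median F error ~0.2 — and a fit initialized at the true
parameters does no better, so this is an information limit of the design,
not an optimizer failure. The original study's own first-component
midpoint carries a +/-29.5 mV standard error, which is the same phenomenon
in real data. Accuracy of 3 mV at this noise level would require roughly
4x less noise or much steeper components; the acceptance suite records
this expectation and its failure explicitly rather than relaxing it. The
practical guidance encoded in the fitter is the degeneracy flag: when
components merge, report that, never a spuriously precise split.

## Expression calling

A well is called positive when its quantification cycle is present and
strictly below 35 (strict inequality as specified in the source protocol).
Cells pass QC iff the housekeeping gene (Gapdh) is positive; bath-control
columns must be all-negative or the run is flagged contaminated. Calls are
only defined for QC-passing cells. Co-expression summaries report, per
population, the anchor-positive percentage and — among anchor-positive
cells — each partner's percentage, always alongside raw counts, with
`percent = round(100 * count / denominator)` and empty denominators
reported as undefined rather than 0. Nearest-integer rounding is used
throughout; the source prints 66% for 30/45 (= 66.7) in one instance,
suggesting truncation there, but nearest-integer (67) is applied
consistently and the discrepancy noted. The Cq generator draws positivity
Bernoulli per gene and population at the observed rates (e.g. 19/44 for
the anchor in the thoracolumbar population) and Cq levels from normals
truncated below threshold around gene-level means (27.2 for the anchor,
16.3 for its partner), so generated matrices reproduce the observed
summary statistics in expectation.

## Problem sizes and seeds

The shipped simulations use 2,000 SNPs for calibration, 200 replicates for
power and 100 replicates per curve-fit recovery study — sizes at which the
binomial standard error of an estimated rate (about 1.5-3.5 percentage
points) is small relative to the asserted margins. Every stochastic
routine takes an explicit seed and leaves the global RNG untouched;
rerunning any script with the same seed reproduces its outputs
byte-for-byte.
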