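---
title: "Pooled barcoded variant screening: models and methods"
author: "manoscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled barcoded variant screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(manoscreen)
```

## The assay and its quantities

The MANO ("mixed-all-nominated-in-one") method profiles hundreds of gene
variants at once. Each variant is expressed from a retroviral construct that
also integrates a random 10-bp DNA barcode, with up to three independently
barcoded clones per variant. Clones are pooled, grown competitively with or
without drug, and the pool composition is read out by amplicon sequencing of
the barcode cassette `5'-CTAGACTGCC-NNNNNNNNNN-GGATCACTCT-3'`.

The analysis chain is:

1. **Barcode counting** — locate the fixed flanks in each read (pair),
   extract the intervening 10-mer, tally per sample.
2. **Quantification** — collapse clones to variants, scale each sample to a
   drug-insensitive reference clone (KRAS G12V in vitro, a GFP clone in
   vivo), and form the *relative growth inhibition*: the ratio of the
   replicate-averaged scaled abundance under treatment to that under
   vehicle. A value of 1 means vehicle-like growth; values near 0 mean the
   variant was depleted.
3. **Dose-response analysis** — arrange inhibition values on an
   afatinib × osimertinib grid (default 8 × 9 log-spaced levels spanning
   500 pM-50 nM and 100 pM-10 µM; 72 combinations), call three-way
   sensitivity per drug, and score Bliss synergy.
4. **In vivo clonal dynamics** — tumor volumes from caliper diameters
   (`π/6·L·S²`), intratumoral variant proportions relative to the GFP
   clone, per-variant relative tumor volume (RTV) against the vehicle arm,
   and paired t tests between arms.

## Barcode extraction

Reads are scanned mate 1 first, then mate 2, forward then reverse
complement; the first stage producing a valid placement wins and, within a
read, the leftmost valid placement is used, which keeps counting
deterministic when the cassette appears twice. Flanks may each mismatch up
to `max_flank_mismatches` bases (default 0; Hamming distance, no indels).
The barcode itself is taken verbatim: every 10-mer is a priori a valid
barcode, so a sequencing error inside the barcode is unrecoverable and the
read surfaces as *unassigned* rather than being rescued. Base qualities are
not consulted. Per sample, `assigned + unassigned + no_context` always
equals the number of read pairs processed — conservation is asserted in the
tests rather than assumed.

Whether the original assay counted one or both mates is not something the
pipeline needs to assume: both-mate scanning is the default and single-end
input is accepted.

## Quantification choices

* **Reference scaling, no depth normalisation.** Scaled abundance is
  `(count + pc) / (reference count + pc)` per sample with pseudocount
  `pc = 0.5`, so the reference row is exactly 1 everywhere and sequencing
  depth cancels in the ratio; a separate depth normalisation would be
  redundant.
* **Pseudocount 0.5** guards zero-count cells while perturbing counts in
  the thousands by well under 0.1%.
* **Clone aggregation by sum** (clones are parallel measurements of one
  variant); `mean` is available when clone numbers differ.
* **Replicate averaging is flat**: scale per replicate, average the scaled
  values across all replicates of a condition, then ratio treated over
  vehicle. The ordering matters when depth varies between replicates and is
  recorded in the run manifest written by the analysis scripts.
* **Competition trajectories** normalise per-day counts to pool proportions
  and fit a least-squares slope of log proportion against day; a variant
  with a zero count at any sampled day gets a flagged `NA` slope instead of
  an extrapolated one.

## Sensitivity classification

The assay's three-way categories (sensitive / partially resistant /
resistant) are qualitative, with no standard numeric cutoffs, so the
classifier uses
survival at the top tested monotherapy dose with defaults

* survival < 0.2 — sensitive,
* 0.2 ≤ survival < 0.5 — partially resistant,
* survival ≥ 0.5 — resistant,

fully configurable and recorded in the output. The mapping is monotone by
construction. "Nonsensitive" in the cross-resistance summary means
resistant *or* partially resistant; this is the reading under which the
reference screen composition the generators emulate (25
afatinib-refractory, 46 osimertinib-resistant, 50 nonsensitive to at least
one, 21 nonsensitive to both, 3 fully resistant to both) is mutually
consistent: 25 + 46 − 50 = 21, 25 − 21 = 4 and 46 − 21 = 25.

## Bliss synergy

For a combination cell with monotherapy inhibitions $E_a$ and $E_o$, Bliss
independence expects $E = E_a + E_o - E_a E_o$; the per-cell score is
$100\,(E_{obs} - E)$ percentage points and the summary is the plain mean
over combination cells only (monotherapy and vehicle cells do not
contribute). Inhibition values outside $[0,1]$ — growth stimulation — are
clipped for scoring only, with a warning; raw values are preserved
elsewhere.

One subtlety worth stating precisely: the simulator's growth law (below) is
Bliss-independent in the *rate multiplier* domain, but the measured
quantity is $\exp(g(s-1)t)$, which is not multiplicative across drugs.
Screens simulated through the full growth law therefore show a small
negative (apparent antagonism) offset that grows with $g\,t$ — about −1
point at the defaults — while surfaces constructed to be multiplicative in
measured survival (`simulate_bliss_surfaces()`) score exactly zero. The
exactness checks use the latter; the former is the realistic screen.

## The four-parameter logistic

`fit_4pl()` fits
$y = \text{bottom} + (\text{top}-\text{bottom})/(1 + (d/\mathrm{IC}_{50})^{h})$
by Levenberg-Marquardt least squares on log-dose, with a deterministic
multi-start over seven log-spaced IC50 seeds spanning the tested doses; the
lowest-RSS converged start wins, and total failure is flagged with
`rss = Inf` rather than an error. Fits whose IC50 falls outside the tested
range are flagged (`in_range = FALSE`): a resistant variant has no
transition in range and its "IC50" is an extrapolation, not a measurement.

## In vivo analysis

Tumor volume is the ellipsoid approximation `π/6 × large × small²` from
caliper diameters (swapped inputs are corrected with a warning). The
per-variant RTV is not given by a printed formula; the package uses the
proportion × volume decomposition

$$\mathrm{RTV}_v = \frac{\overline{p_{v,\text{treated}}}\;
\overline{V_\text{treated}}}{\overline{p_{v,\text{vehicle}}}\;
\overline{V_\text{vehicle}}},$$

the most direct reading of "relative tumor volume of each variant compared
with the vehicle group": summed over variants it reproduces each arm's mean
total volume, so the abundance-weighted mean RTV equals the total-volume
ratio. Proportion-only RTV is computable by passing unit volumes.
Aggregation across mice is the arithmetic mean of proportions; in vivo
calls reuse the in vitro thresholds on RTV for comparability.

## The synthetic-data generator

Every stage is verifiable without external data because the generator
produces screens with known ground truth.

* **Clone model.** Each clone has a per-day log growth rate `g`
  (≈ 0.6/day, a Ba/F3-like doubling of ~28 h, jittered N(0.6, 0.05²)) and
  per-drug Hill parameters. Pools grow deterministically as
  $N_v(t) = N_v(0)\exp(g_v\, s_v(c)\, t)$ with survival multiplier
  $s_v(c) = \prod_d [1 - I_{max,d}/(1 + (\mathrm{IC}_{50,d}/c_d)^{h_d})]$;
  stochasticity enters only at sequencing, as multinomial (optionally
  Dirichlet-overdispersed) read sampling. At infinite depth the recovered
  inhibition converges to $\exp(g(s-1)t)$, the closed form the tests check.
* **Archetypes.** Four canonical EGFR-TKI response patterns: sensitive to
  both (L858R-like; afatinib IC50 ≈ 2 nM, osimertinib ≈ 20 nM), resistant
  to both (exon-20-insertion-like; IC50s ~40× above the top tested doses),
  afatinib-only resistant (T790M-like) and osimertinib-only resistant
  (L718V/V802F-like). IC50s are jittered lognormally (sdlog 0.25). These
  values are synthetic stand-ins chosen on pharmacological grounds — no
  per-variant growth or potency parameters are available for the real
  clones — and are never presented as estimates of them.
* **Reads.** `emit_fastq()` plants `flank5+barcode+flank3` at a random
  offset in random background, mate 2 the reverse complement, independent
  substitution errors per mate. No indels and no realistic quality model —
  by design; passing round-trip tests therefore show correctness of the
  counting logic, not robustness to every Illumina artifact.
* **Xenografts.** The same growth law with the day-varying drug set of a
  regimen at fixed effective in vivo concentrations (afatinib 20 nM,
  osimertinib 200 nM — above the sensitive IC50s, far below the resistant
  ones). Gefitinib reuses each clone's afatinib Hill parameters at its own
  concentration, reflecting the near-identical variant spectra of first-
  and second-generation TKIs. In-culture growth rates are halved in vivo
  (`growth_scale = 0.5`, a ~2.3-day xenograft doubling). Volume is
  `1e-6 mm³ × cells` with lognormal measurement noise (sdlog 0.1), split
  into diameters by a lognormal eccentricity (sdlog 0.1); per-mouse
  inoculum jitter is lognormal (sdlog 0.2). Treatment runs from day 6 with
  the sequential-regimen switch on day 16 and the experiment ending on
  day 30 — the schedule under which an afatinib-resistant dominant clone
  makes the combined arm smaller than afatinib-first, which in turn beats
  osimertinib-first (the afatinib-first arm ends with 14 days of
  osimertinib suppressing the dominant clone, the reverse arm ends with 14
  days of unchecked regrowth). Note the model is cytostatic
  ($s \in [0,1]$): drugs arrest clones rather than shrink them.
* **Aggregate emulators.** `simulate_catalog()` and
  `simulate_call_table()` generate tables whose *marginal composition*
  matches the reference aggregate composition (FFA scores 213/29/50/65 of 357,
  282 Ba/F3 transformers, 26 novel oncogenic; call cells 3/18/4/25 of
  282); everything else about the records is cosmetic and labelled
  synthetic. They exist so that the summary arithmetic can be exercised
  end-to-end against known percentages.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run screens of 40-50 variants
(126-156 clones) at 10⁵-10⁶ reads per sample, 1,000 random surfaces for
the Bliss exactness check, 100 noisy curves for the 4PL study, and 10
seeds × 3 mice per arm for the regimen comparison — sizes at which the
sampling-theory tolerances used in the tests (3 multinomial standard
errors; median IC50 error < 5% at 1% response noise) are well separated
from failure modes. Ties in rank-based checks are driven by resistant
variants whose true survivals cluster near 1; rank correlations are
computed across the full variant × condition matrix for that reason.
Degenerate inputs are flagged, never imputed: missing surface cells stay
`NA`, zero-variance paired differences return a flagged `NA` p value, and
a zero reference count falls back to the pseudocount with the sample
recorded.

## Known limitations

* The cutoffs separating the three sensitivity categories, the RTV
  decomposition, and the minimum-abundance filter for in vivo variants are
  package choices where the published description is qualitative; all are
  configurable and recorded in outputs.
* The growth model has no carrying capacity, no clonal evolution during
  treatment, and no cell death (arrest only); real regimen dynamics with
  regressing tumors are richer than the simulator's.
* Barcode errors are unrecoverable by design (no error-correcting map);
  at 0.1% substitution error this costs ~1% of reads, which reference
  scaling cancels to first order.
* `simulate_catalog()` emulates marginal compositions, not the joint
  structure of real annotation tables; conclusions about covariation
  between, say, exon and FFA score cannot be drawn from it.
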