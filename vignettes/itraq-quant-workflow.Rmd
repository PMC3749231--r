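---
title: "From PSMs to differential proteins: the itraq4 workflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From PSMs to differential proteins: the itraq4 workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itraq4)
```

## The measurement and its error structure

iTRAQ 4-plex labeling lets four samples be quantified in one LC-MS/MS
run: each sample's peptides carry an isobaric tag that releases a
reporter ion at m/z 114, 115, 116 or 117 during fragmentation, and the
reporter intensities encode relative peptide abundance across the four
channels. In the xenograft design this package targets, the channels
carry two control tumors and two treated tumors — either four animals
(biological duplicates, C1/C2/T1/T2) or two animals each split into two
preparations (technical duplicates, C1a/C1b/T1a/T1b).

Two error sources matter downstream and are modeled explicitly:

* **technical error** — everything from protein extraction through
  labeling and MS measurement, acting independently on every
  reporter measurement (log2 sd τ);
* **biological variation** — real animal-to-animal differences in a
  protein's abundance, shared by technical replicates of the same tumor
  (log2 sd β per protein per tumor).

A technical-duplicate run sees only τ; a biological-duplicate run sees
both. This asymmetry is what the variance decomposition exploits.

## Peptide qualification

Only a subset of identified PSMs carries trustworthy quantitative
signal. Four criteria, applied in order (1 labeled, 2 confident,
3 unique, 4 dynamic range), define the qualified set; the report counts
each rejected record under its first failing criterion, because no
multiplicity rule is standard and first-failure attribution makes the
counts sum to the number rejected. Confidence is operationalized as ion
score strictly greater than the identity-threshold score: a score
exactly at the threshold is not "higher" and is rejected. The
dynamic-range rule (every channel > 0, mean ≥ 30 ion counts) is applied
to **raw** intensities, before normalization: selection precedes
normalization in the workflow, and the 30-count floor is an instrument
dynamic-range statement about measured ion counts, not about rescaled
signal. Decoys never enter quantitation; they exist to estimate the
identification FDR as D/R × 100%.

## Normalization

Global channel biases (unequal loading, labeling efficiency) multiply
every intensity in a channel by a common factor, so normalization is
multiplicative: `x = x0 * N_X`. Fitting rules:

* **Method 1** — equal summation: `N_X = sum(x_ref) / sum(x_X)`.
  Dominated by the brightest peptides.
* **Method 2 (default)** — median log2 peptide ratio to zero:
  `N_X = 2^(-median(log2(x_X / x_ref)))`. After application the median
  log2 ratio of every channel is exactly zero (a floating-point-exact
  post-condition, tested at 1e-12). Robust to a minority of truly
  changing peptides; this is the method of choice whenever most of the
  proteome is unchanged.
* **Methods 3 and 4** — trend-line variants. The one-line descriptions
  these methods circulate under do not pin down the fit, so the
  implementations here are declared interpretations: method 3 is a
  least-squares line through the origin of `x_X` on `x_ref` (factor =
  1/slope); method 4 fits a unit-slope offset on log2 signals (factor =
  `2^(-mean offset)`). Both recover a pure channel scaling exactly.
* **Method 7** — protein-level median centering, an additive log2 shift
  applied after rollup, per comparison.

Multi-Q's internal normalization factors (sometimes numbered methods 5
and 6 in comparisons) are an external tool's output with no published
formula and are deliberately not implemented.

The quality metric for comparing methods is the mean of per-protein S
values under a paired design (`evaluate_normalization()`): a perfect
normalization leaves the two paired treatment/control ratios of each
protein in agreement, so mean S near zero indicates removed bias.
`evaluate_reproducibility()` reports the squared Pearson correlation of
two channels' raw intensities — the standard scatter-plot check that
technical duplicate channels track each other.

Median convention: the median of an even-count set is the mean of the
two central values (R's default), making the method-2 post-condition
exact for even n as well.

## Protein quantitation

The rollup is the sum of intensities: per protein, reporter intensities
of its qualified peptides are summed per channel, and each abundance
ratio is a quotient of two sums. This weights peptides by intensity —
a deliberate choice: quotient-of-sums has lower error than the
unweighted mean of peptide ratios in the presence of low-intensity
outliers, and it is computationally trivial. The grouping key is the
record's accession set as assigned upstream; re-running protein
inference is out of scope (only unique peptides are qualified).

For the xenograft species problem the rule is three-case, over the union
of species tags in the protein's peptide set: human-only kept,
mouse-only excluded, shared (human+mouse, i.e. sequence conserved
between species) kept but flagged `+` in every report. Shared-peptide
intensities are summed at full weight; the flag, not a down-weighting,
carries the ambiguity, matching standard reporting practice.

## Differential selection: R, S, and the cut-offs

With two controls and two treatments, each protein has four
treatment/control ratios and

* `R = mean of the four log2 ratios` (2^R = linear fold change),
* `sigma_R = 0.5 * sqrt(log2^2(C2/C1) + log2^2(T2/T1))` — algebraically
  identical to the population sd (divisor 4) of the four log2 ratios,
  an identity the test suite verifies against a brute-force oracle on
  10^4 random draws,
* `S = 0.5 * (log2(T1/C1) - log2(T2/C2))` — obtained by exchanging C2
  and T2 in the R equation and simplifying (also oracle-verified). S is
  blind to the true fold change (it cancels) and nonzero only through
  error, so the spread of S across proteins estimates the error of R.

Assuming normal errors, cut-offs are placed at `M_R ± z*sigma_S` with
z = 1.96 (P < 0.05); classification uses strict inequalities, so a
protein exactly on a cut-off is unchanged. S is kept signed — absolute
values are never taken before the sd.

Numerical conventions, chosen where the convention is genuinely open:

* `sigma_S` uses the **sample** sd (divisor n−1) by default, exposed as
  `sd_type` since population is equally defensible at cohort size;
  `sigma_R`'s divisor-4 population form is fixed by the closed-form
  identity above.
* Proteins must carry all four ratios to enter `M_R`/`sigma_S`
  estimation (rollup guarantees this for every quantified protein).
* Reference worked values: with M_R = 0.0037 and sigma_S = 0.4256 the
  upper cut-off is 0.8379. The matching published lower cut-off −0.8306
  and biological component 0.2461 both show a one-in-the-last-digit
  rounding asymmetry against the printed inputs (the arithmetic gives
  −0.8305 and 0.2460): these are artifacts of rounding intermediate
  statistics before the final operation. This package reproduces the
  arithmetic, not the rounding, and its acceptance checks compare at
  4 d.p. with a ±0.0005 band.

The decomposition `sigma_S(b) = sqrt(sigma_S^2 - sigma_S(t)^2)` assumes
technical and biological errors independent and additive on the log2
variance scale; it errors out (rather than returning 0) when
`sigma_S(t) > sigma_S`, since a negative variance means the two inputs
are inconsistent and silently clamping would hide that.

## The synthetic world

`simulate_psm()` emits PSM tables from a generative model that mirrors
the error structure above. Per protein p, peptide i, channel X of tumor
j, the log2 intensity is

```
mu_p + eps_i + delta_p*[X treatment] + b_pj + log2(bias_X) + e_pijX
```

with `b_pj ~ N(0, beta^2)` drawn once per protein per tumor (shared by
technical replicate channels of a tumor — the linkage that makes
sigma_S(t) technical-only) and `e ~ N(0, tau^2)` per measurement.
`b` is per-protein-per-tumor rather than one global offset per tumor
because a global offset is exactly what normalization removes; the
protein-wise component is what survives into sigma_S(b).

Defaults, chosen once as a realistic xenograft study and not revisited:

| parameter | default | rationale |
|---|---|---|
| `n_proteins` | 2000 | cohort scale at which sd estimates stabilize |
| `peptides_mean` (geometric, min 1) | 4 | qualified-peptides-per-protein ratio of a moderate-depth run |
| `frac_differential` | 0.054 | ~5% of a proteome responding, as in a typical perturbation |
| `fc_mean`, `fc_sd` | 1.2, 0.3 (log2, random sign) | called proteins cluster around 2–2.5 fold |
| `base_log2_mean`, `base_log2_sd` | 9, 2 | reporter ion counts centered ~500, wide dynamic range |
| `peptide_log2_sd` | 0.8 | peptide-to-peptide ionization spread |
| `channel_bias` | 1, 1.15, 0.92, 1.08 | ≤15% loading bias, the size normalization must fix |
| `technical_sd` (tau) | 0.3473 | per-measurement log2 error matching a technical-duplicate S spread |
| `biological_sd` (beta) | 0.2461 | per-tumor-per-protein variation matching the decomposed component |
| `frac_mouse`, `frac_shared` | 0.05, 0.30 | host contamination and human/mouse-conserved peptides are both common in xenografts |
| `decoy_rate` | 0.025 | a 2–3% identification FDR |
| `unlabeled_rate` | 0.004 | >99% labeling efficiency |
| `low_confidence_rate`, `degenerate_rate` | 0.01, 0.01 | criterion-2/3 violations for qualification bookkeeping |
| `low_intensity_rate` | 0.03 | records below the 30-count dynamic-range floor |

Nuisance records are injected on disjoint row sets in exact configured
counts, so the qualification report's per-criterion numbers equal the
generator's truth — a bookkeeping invariant the tests assert exactly.
`make_duplicate_pair()` generates a technical and a biological
experiment on one shared proteome, the shape the variance decomposition
consumes.

What the generator does **not** emulate: spectra and peak picking,
chromatographic fractionation, iTRAQ isotope impurity and the ratio
compression it causes, missing channels, and intensity-dependent
(heteroscedastic) noise. A green end-to-end test therefore establishes
that the statistics behave as designed under the stated error model —
not that any instrument artifact is handled.

One propagation subtlety, documented because it shapes the recovery
test: with m peptides summed per protein, the technical component of a
protein-level ratio shrinks roughly like tau/sqrt(m_eff) (biological
variation does not shrink — it is per protein, not per peptide). So
sd(S) from a technical run estimates tau itself only at one peptide per
protein; the tau/beta parameter-recovery check runs the generator with
`peptides_dist = "fixed", peptides_mean = 1`, where sd(S_technical) =
tau and the quadrature decomposition returns beta, both analytically.
At the multi-peptide default, sigma_S(t) is the *protein-level*
technical error — smaller than tau, which is the correct quantity for
cut-offs but not a direct estimate of the per-measurement sd.

Similarly, the exact-recovery check (every protein at delta = 1, no
noise) rolls up raw qualified peptides: median-centering normalization
assumes most proteins are unchanged and would re-center a
proteome-wide shift to zero. That is correct behavior of method 2, not
a defect, and the test respects it.

## Degenerate inputs and numerical edges

* Ratios require strictly positive intensities; qualification guarantees
  this for everything downstream, and the ratio functions error on
  non-positive input rather than emitting Inf/NaN.
* `derive_cutoffs` needs ≥ 2 S values; with zero spread both cut-offs
  collapse onto M_R and every off-median protein is called — the honest
  consequence of claiming zero error.
* All generator output is deterministic given `seed`; written tables are
  byte-identical across reruns.
* Method-2 and method-1 post-conditions are enforced to 1e-12 in tests;
  fits are invariant to record order and to global rescaling of all
  channels.

## Known limitations

* No ratio-compression correction (isotope impurity, co-isolation);
  fold changes from real iTRAQ data are typically compressed toward 1.
* A single global z cut-off, as the method defines; no per-protein
  moderated variance and no multiplicity (FDR) control across proteins.
* Protein grouping trusts the upstream engine's assignments.
* Methods 3/4 are interpretations of underspecified one-line
  definitions and are labeled as such.
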