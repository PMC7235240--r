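---
title: "Diagnosing reverse-transcription bias with nested titrations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing reverse-transcription bias with nested titrations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cq2f)
```

## The problem

A qPCR measurement of gene expression is really two serial enzymatic
assays: reverse transcription (RT) of RNA into cDNA, then exponential
amplification of that cDNA. The amplification step is routinely calibrated
— dilution series, efficiency estimates, melt curves — but the RT step is
usually taken on faith. That faith is misplaced: RT capture of a given
amplicon can depend non-linearly on total RNA input, differently for each
amplicon and each enzyme. A reference gene whose RT response saturates
early will make every normalised target appear regulated; two aliquots of
the same RNA that differ only in integrity can appear differentially
expressed 2-fold and more.

The diagnostic this package implements is a *nested titration*: a 2-fold
dilution series of RNA into the RT (the **RT axis**) crossed with a 2-fold
dilution series of each resulting cDNA into the qPCR (the **qPCR axis**).
Both axes make the same prediction under ideal behaviour — doubling the
input lowers Cq by exactly one cycle — so comparing them isolates where
the non-linearity lives. The qPCR axis acts as the internal control: if it
titrates cleanly while the RT axis does not, the assay chemistry is fine
and the RT step is the culprit.

## The Cq2f statistic

For every *adjacent* 2-fold pair on an axis we compute

> Cq2f = Cq(lower input) − Cq(higher input),

the Cq increase per 2-fold dilution. Ideal dose response gives Cq2f = 1;
Cq2f near 0 means the readout ignored the input. Summaries are the
arithmetic mean, the sample SD (n−1 denominator — groups are small, often
3 pairs) and the pair count, either pooled or per grouping (typically
amplicon × kit). Pooled grand means equal the pair-count-weighted mean of
group means, so "overall" numbers never depend on how groups are carved.

Three deliberate restrictions keep the statistic's definition exact:

* Only adjacent pairs (600↔300, 300↔150, 150↔75 ng) count — this is the
  only reading consistent with the pair cardinalities of the built-in
  designs (e.g. 648 RT-axis pairs in `exp1` = 3 RNAs × 3 kits × 8
  amplicons × 3 dilutions × 3 adjacent dose pairs).
* RT-axis pairs are formed separately at each qPCR dilution level, never
  after averaging across levels.
* A missing member simply removes its pairs; a 4-fold gap is never halved
  into synthetic 2-fold pairs.

Mean Cq2f per group is classified as `linear` (≥ 0.75), `saturated`
(≤ 0.25) or `compressed` in between. The defaults were chosen to separate
the canonical exemplars of each behaviour (≈0.95 vs ≈0.45 vs ≈0.13) and
are arguments, not constants. We deliberately do not fit full standard
curves (slope/R²/efficiency): the pairwise statistic needs no model, keeps
its units in Cq per doubling, and degrades gracefully with missing wells.

## Replicate condensation

Triplicates are condensed by the **best-duplicate rule**: the mean of the
two closest replicates, with their absolute difference as the spread. This
is a cheap, deterministic guard against the single aberrant well (dust,
bubble) that dominates qPCR replicate failure; mean and median policies
are provided and give closely similar results on well-behaved data. Two
non-obvious choices:

* **Ties** (e.g. 10.0, 10.2, 10.4) are broken toward the pair with the
  lower mean Cq — deterministic, and it favours the stronger signal — and
  flagged `TIE_BROKEN`.
* **Undetermined wells** (no threshold crossing in 40 cycles) are excluded
  before pair selection; if exactly two finite values remain they form the
  duplicate, flagged `UNDETERMINED_PRESENT`. Groups with fewer than two
  finite values are dropped and reported, never imputed. Undetermined is
  preserved through I/O as the literal token — it is a censoring state,
  not "Cq 40".

Condensed values above Cq 30 are flagged `HIGH_CQ` (single-molecule
stochastic territory) but kept; a stricter pipeline can drop them. RT0 and
RT− negative controls are checked against a configurable threshold
(default Cq 35): any finite control reading below it fails the QC gate.

## The generative model

Every analysis stage is testable without wet-lab data because the package
ships a generative simulator of the whole experiment. The noiseless Cq of
one well is

> T = α(a, r) · s(a)^frag · M / (1 + M/K(a, k)),
> Cq = β(k) − log(T/d) / log(1 + E)

with α the template abundance per ng for amplicon *a* in RNA *r*, M the
RNA mass into the RT (ng), d the qPCR dilution factor, β(k) a kit-level
intercept, E the qPCR efficiency, s(a) the fragmentation survival factor
(applied when the RNA is flagged fragmented) and K(a, k) the RT
saturation constant. Replicate noise is Gaussian on the Cq scale,
homoscedastic, default SD 0.19 Cq — a typical triplicate dispersion for
careful plate work. Simulated Cq beyond the 40-cycle horizon, and all
negative-control wells, are emitted as Undetermined.

The saturation law is hyperbolic (Michaelis–Menten in *total* RNA input):
one parameter per amplicon × kit, smooth, and with the observed signature
— Cq2f drifting from 1 toward 0 as input rises. Saturation is driven by
total input M rather than the amplicon's own template amount because the
plausible mechanisms (priming-oligo sequestration by abundant transcripts,
enzyme capacity) act through the bulk reaction. On the RT axis the model
gives the closed form

> Cq2f(M, K) = 1 + log2((1 + M/K) / (1 + 2M/K)),

which equals 1 at K = ∞, is strictly decreasing in M/K, and is what
`fit_saturation()` least-squares-fits back to observed pairs to estimate
K. The fit is one-dimensional in u = 1/K (a coarse log-spaced scan then a
golden-section polish, tolerance 1e−14), so "no saturation" is the clean
boundary u = 0: when the flat model y ≡ 1 fits at least as well, or the
optimum exceeds K = 10⁶ ng, the fit reports K = ∞ with
`saturation_detected = FALSE` rather than an astronomically large number.

Defaults: E = 1 (perfect doubling — qPCR-axis grand means in practice sit
within a percent of 1, and the qPCR step is not what this package
diagnoses), σ = 0.19 Cq, and two presets. `ideal` (K = ∞, s = 1, σ = 0) is
the exact textbook limit: every Cq2f equals 1 identically, which anchors
the exactness tests. `paperlike` is an illustrative, hand-chosen (not
fitted) parameter set reproducing the qualitative pathologies of real
nested titrations: its saturation constants were inverted from published
exemplar Cq2f values (e.g. K ≈ 170 ng makes the mean over the 75–300 ng
dose pairs equal 0.45), its survivals encode strong template loss for
coding amplicons (s = 0.25 for the long reference transcript, a +2 Cq
shift) against protection of the structured U1 snRNA (s = 1.6, a −0.68 Cq
shift), and one genuine 2-fold biological difference (OAZ1 between the two
cell-line RNAs) is included so that "real" and artifactual DE coexist.

### What the simulator does and does not emulate

It emulates the *structure* of a real nested titration — grid, controls,
replicate noise, saturation, fragmentation shifts, detection censoring —
so passing tests demonstrate that the statistics recover the model's truth
from realistically shaped data. It does not emulate sequence-level
chemistry (GC effects, priming thermodynamics), inter-plate batch effects,
heteroscedastic late-cycle noise (an optional extra-variance term above
Cq 30 exists but is off by default), or — importantly — *sample-dependent*
saturation: K varies by amplicon and kit but not by RNA. One documented
consequence: in dose-matched ΔΔCq between two intact RNAs the saturation
term cancels exactly, so the simulator cannot produce the dose-dependent
apparent DE seen in real data when two samples saturate differently; that
artifact is reachable here only through fragmentation (via s) or
cross-kit comparisons. Conclusions about real data should rest on running
the diagnostics on real titrations, which is what the package is for.

## The report gate

`qc_report()` bundles the stages — completeness validation, dispersion,
negative controls, both-axis Cq2f summaries with labels, configured ΔΔCq
recipes, fragmentation shifts for every matched RNA pair — and encodes the
actionable recommendation as an exit status: nonzero when any amplicon ×
kit RT response is saturated, or when a recipe's fold change drifts across
doses by more than 1.5-fold (ΔCq 0.58 — the scale of fluctuation that
reference-gene normalisation can legitimately absorb). Every number in the
human-readable summary is also in `report.json`; re-running on the same
inputs is byte-identical.

## Numerical and testing notes

Exactness claims (ideal-preset Cq2f ≡ 1, pair-count identities) are
asserted exactly, not to a tolerance — the arithmetic involved is closed
under doubling. Brute-force oracles (exhaustive pair minimisation for the
best-duplicate rule, matched-coordinate scans for pair enumeration) back
the fast implementations on thousands of randomised cases. Parameter
recovery is checked both noiselessly (K = 300 recovered to 1e−6 relative)
and as a seeded Monte-Carlo calibration (200 runs at σ = 0.05 Cq2f noise,
72 observations over three dose pairs: K = 150 recovered within 15% in
well over 90% of runs). The full `exp1` grid (2592 sample wells plus
controls) simulates and analyses in well under a second, so all tests run
at the experiment's native size.

Known limitations, beyond the simulator's scope above: the dose-matched
ΔΔCq analyses require equal RT inputs in both conditions by design
(cross-dose comparisons are only made deliberately, via
`apparent_de_across_doses`); multiple reference amplicons are combined as
the arithmetic mean of their Cq values (the geometric mean of linear
quantities), which assumes roughly comparable reference reliability; and
no efficiency-corrected (Pfaffl-type) quantification or DE significance
testing is attempted — the package measures technical dose-response bias,
a prerequisite for, not a replacement of, expression inference.
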