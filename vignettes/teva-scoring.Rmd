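---
title: "Scoring ex vivo explant drug response against in vivo xenograft efficacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring ex vivo explant drug response against in vivo xenograft efficacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tevascore)
library(dplyr)
```

## The problem

Tumor explant assays expose small (roughly 2 x 2 x 2 mm) pieces of a
patient-derived xenograft (PDX) to candidate drugs for 24 hours, then read
out proliferation (Ki67 IHC) and apoptosis (TUNEL) on stained sections. The
promise is a fast, cheap surrogate for the weeks-long mouse efficacy study
run on the same PDX. For that surrogate to be useful, a drug's ex vivo
response score must rank drugs the same way the in vivo study does.
`tevascore` implements the analysis side of this comparison: IHC
quantification, the two response scores, and their concordance.

## The scores

**Ex vivo (VitroF).** Each stained section contributes one *object
frequency*: positive nuclei divided by the annotated tumor area, in
pcs/mm^2. Normalizing to the tumor area (rather than to the whole section)
matters because the tumor-to-stroma ratio varies between sections of the
same explant. Group mean frequencies are normalized so the vehicle control
equals 100, and the score combines both assay arms with equal weight:

$$\mathrm{VitroF} = \tfrac12\,\frac{Ct_{Ki67}}{Tr_{Ki67}}
                  + \tfrac12\,\frac{Tr_{TUNEL}}{Ct_{TUNEL}}$$

A drug with no effect scores 1; suppressed proliferation or induced
apoptosis raises the score. The two terms deliberately capture different
pharmacology — a purely cytostatic drug moves only the first term, a purely
cytotoxic one only the second.

**In vivo (VivoF).** Caliper pairs are converted to volumes with the
modified-ellipsoid rule $V = L \cdot W^2 \cdot \pi/6$, where $W$ is the
smaller of the two orthogonal diameters. At the penultimate and last
measurement days shared by the treatment and vehicle arms, the treatment
group mean is normalized to the vehicle mean (control = 100):

$$\mathrm{VivoF} = \tfrac12\,\frac{CTV}{TTV_{\text{2nd last}}}
                 + \tfrac12\,\frac{CTV}{TTV_{\text{last}}}$$

Using the two last days rather than a growth-rate fit keeps the score
robust to the short (about two-week) measurement window and matches how the
score is operationally defined.

**Concordance.** Per-drug (VitroF, VivoF) pairs are summarized by the
Pearson correlation and a least-squares line, computed from sums of
products and cross-checked in the tests against `stats::cor()` and
`stats::lm()`. Spearman's rho and a seeded permutation p-value (10,000
shuffles by default) are reported as labeled extras; the headline statistic
stays the Pearson r, and the number of pairs is always surfaced next to it
because correlations over 3-5 drugs are fragile.

## Design choices where the procedure was open

* **Aggregation order.** Frequencies are averaged per group first, then one
  ratio per group is formed (ratio of means, not mean of per-explant
  ratios). This mirrors how grouped bar values are normalized to a control
  bar and is the more stable estimator at 4 explants per group.
* **Zero handling.** The score is undefined at zero denominators. The
  treated Ki67 normalized value is floored at 1 (1% of control), capping
  the proliferation term at 50; a zero vehicle TUNEL mean is floored at
  1 pcs/mm^2 and the result flagged `floored`. Both floors are visible in
  the output rather than silent.
* **Scored timepoints.** The penultimate and last *shared* days are used.
  Mice missing one of those days are dropped from that day's mean with a
  warning; no imputation.
* **Normalization day.** The vehicle mean is taken at each scored day
  (not at baseline), matching how growth curves are compared.
* **Replicate uncertainty.** VitroF is reported with a seeded percentile
  bootstrap over explants (1,000 resamples by default). The interval is an
  addition; the point score is untouched.
* **Randomization.** `allocate_groups()` implements the standard enrollment
  restrictions for PDX efficacy studies: volumes at the extremes are
  excluded up front, and the remaining mice are dealt to arms in serpentine
  order of sorted volume, which balances group means and SDs
  deterministically (ties broken by mouse id).

## What the synthetic generator emulates

The generator produces the three data types the analysis consumes, under
known effects, so every stage can be tested against ground truth.

* **Explant staining tables.** Positive counts are Poisson (optionally
  negative binomial via `count_dispersion`) with mean density x area;
  annotated areas are gamma-distributed. Defaults: vehicle Ki67 density
  400 pcs/mm^2, TUNEL 50 pcs/mm^2, area 1.5 mm^2 (CV 0.2), 4 explants per
  group - a plausible scale for stained PDX sections and the typical size
  of a drug panel arm.
* **Caliper series.** Latent volumes follow exponential growth
  $V(t) = V_0 e^{r(1-g)t}$ from about 100 mm^3 at randomization
  (per-mouse CV 0.1), r = 0.08/day, measured on days 1, 4, 7, 10, 13.
  Latent volume is decomposed into two diameters consistent with the
  caliper formula (sphere-equivalent by default; `aspect_ratio` > 1
  exercises the smaller-dimension rule), then each diameter gets
  multiplicative lognormal noise (CV 0.05).
* **IHC tiles.** DAB-like grayscale tiles with non-overlapping disk nuclei
  placed uniformly inside the annotation; the true count is returned. Disk
  placement keeps a 2-pixel margin beyond touching so each rasterized
  nucleus stays one 8-connected component - the regime in which exact count
  recovery is a meaningful contract.
* **Drug effect panels.** `sample_drug_effects()` draws one latent potency
  per drug and maps it to the Ki67 multiplier, TUNEL multiplier, and growth
  inhibition. Two noise scales are distinct by design: the latent
  perturbation across components is small (`effect_sd = 0.05`), while
  measurement noise (counts, calipers) is moderate. The dominant
  stochasticity in a simulated study should come from measurement, not from
  the latent biology; making the component coupling loose would change the
  question from "can the pipeline recover concordance" to "is there
  concordance to recover". In the independent regime the ex vivo and
  in vivo potencies are unrelated, giving the null against which recovery
  is judged.
* **Determinism.** One master seed; each stream (explants, growth, tiles,
  bootstrap, permutations) derives its own child seed, so outputs are
  byte-reproducible and streams stay independent.

A `deterministic = TRUE` scenario replaces every sampling step with its
expectation (counts may then be fractional). In that mode the scores have
closed forms - VitroF $= 0.5/p + 0.5a$ for multipliers $(p, a)$ and VivoF
$= 0.5\,e^{rgt_{pen}} + 0.5\,e^{rgt_{last}}$ - which the tests verify
exactly.

What the generator does **not** emulate: tumor microenvironment and stroma
beyond a binary tumor mask, pharmacokinetics, immune effector mechanisms
(relevant to antibody drugs in vivo), staining artifacts, and nucleus
overlap or clumping. Passing tests therefore show the *analysis* is
correct and well-calibrated under the stated models; they are not evidence
about wet-lab or real-slide behavior, where the absolute object counts of
any quantification software depend on unpublished detection parameters.
Only the control-normalized ratios are designed to transfer.

## IHC quantification choices

Objects are 8-connected components of pixels at or above a global
threshold inside the annotation mask, with components smaller than
`min_object_px` (default 4 px) discarded. There is no color deconvolution
and no watershed splitting: the commercial software being emulated does not
publish its algorithm, so the simplest reproducible pipeline is used and
validated against generator ground truth. Frequency is invariant to any
intensity rescaling that preserves threshold ordering, and quantification
is additive: merging tiles equals pooling counts and areas.

One unit note: object frequency is per mm^2 of annotated section area.
Sections are two-dimensional; a per-volume unit sometimes quoted for such
readouts is a misprint this package does not reproduce.

## Numerical and reporting details

* Scores and correlations are plain doubles; no rounding happens before
  serialization (`readr::write_csv`, `jsonlite::write_json` with
  `digits = NA`).
* `teva_run()` writes a manifest (tool version, seed, parameters, input
  fingerprints, wall-clock timestamp). Repeated runs under the same seed
  are byte-identical in every data output; the manifest differs only in
  its timestamp line, which records provenance, not results.
* Permutation p-values use the add-one estimator
  $(1 + \#\{|r_\pi| \ge |r|\})/(B + 1)$, so they are never exactly zero.
* Pipeline errors carry the failing stage name (`[explant_scoring] ...`).

## Problem sizes used in the test suite

The suite simulates studies at the scale the defaults describe: 5-drug
panels, 4 explants and 6 mice per arm. Moment-recovery checks use 10^4
count draws (3-SE tolerance); concordance recovery uses 200 replicate
studies per regime; quantification exactness uses 100 seeded 0.4-mm tiles;
allocation balance uses 100 random 16-mouse enrollments (4 extremes
excluded, 3 arms). These sizes make the Monte-Carlo assertions stable
without being wasteful.

## A worked run

```{r example, eval = FALSE}
cfg <- scenario_config(
  seed = 1,
  drug_effects = sample_drug_effects(5, seed = 1, concordant = TRUE)
)
report <- teva_run(cfg, out_dir = "teva_out")
report$concordance
glance(report$concordance)
autoplot(report$concordance)
```

## Known limitations

* Concordance over 3-5 drugs has wide sampling error; the permutation
  p-value and `n` are reported for this reason, but no multiplicity
  control is attempted across drug panels.
* VivoF depends only on the two last shared days; it does not use the full
  growth curve and is sensitive to the study's end-day choice.
* The score floors (complete cytostasis, zero control apoptosis) are
  pragmatic caps, not estimates; flagged results should be read as "at
  least this large".
* The IHC module assumes the annotation mask is given and correct;
  annotation quality is outside its scope.
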