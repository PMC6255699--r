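---
title: "Quantifying leaf xylem embolism from microCT scan pairs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf xylem embolism from microCT scan pairs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(xylemct)
library(dplyr)
```

## The measurement problem

Drought places the water column in plant xylem under increasingly negative
pressure. When a conduit's air-seeding threshold is passed, the conduit
embolizes — fills with gas — and stops conducting. The standard resistance
index is **P50**, the xylem water potential (MPa) at which half of the
hydraulic conductance is lost, together with the slope **S** of the
vulnerability curve at that point.

Synchrotron phase-contrast microCT makes embolism directly visible in a leaf
vein cross-section: water-filled conduit lumina appear grey, gas-filled
lumina distinctly dark. The measurement protocol this package implements
works on *scan pairs*:

1. scan the intact vein at a known xylem water potential $\Psi$ (the
   *pre-cut* image): dark lumina are the conduits already embolized;
2. cut the vein within the scanned region and rescan (the *post-cut*
   image): cutting embolizes 100% of the functional conduits, so every
   conduit lumen is now dark — the maximal-conductance reference.

Each detected lumen of area $A_C$ is treated as a circular tube of diameter
$D = 2\sqrt{A_C/\pi}$ with Hagen–Poiseuille theoretical conductance

$$K_{TH} = \frac{\pi \rho D^4}{128 \eta},$$

with $\rho = 0.9982$ and $\eta = 1.002$ as conventionally printed. The
constants cancel in every reported ratio, so $K_{TH}$ is kept in internal
(printed-constant) units and never reported in SI; a dimensional subtlety —
the formula as written is a conductivity per unit length rather than a
conductance — is therefore harmless and deliberately left alone.

The theoretical percent loss of conductance of one scan pair is

$$\mathrm{PLC}_{K_{TH}} = 100 \cdot
  \frac{\sum_{\text{embolized (pre-cut)}} K_{TH}}
       {\sum_{\text{all (post-cut)}} K_{TH}},$$

i.e. the conductance fraction already lost before cutting. A fully hydrated
vein gives 0, a fully embolized one 100. Values are clamped to $[0, 100]$
because segmentation noise can otherwise nudge the ratio past 100.

Plotting PLC against $\Psi$ over many leaves at different drought stages and
fitting

$$\mathrm{PLC}(\Psi) = \frac{100}{1 + \exp\!\big(\tfrac{S}{25}(\Psi - b)\big)}$$

yields $b$ (the P50; $\mathrm{PLC}(b) = 50$ exactly) and $S$ (minus the
curve's slope at $b$, in % per MPa).

## What the synthetic generator emulates

No public image archive accompanies this kind of beamline campaign, so the
package ships a generator that plays the beamline's role and carries ground
truth through every stage:

* **Conduit populations** — lumen areas are lognormal (positive,
  right-skewed, as conduit areas are), parameterised by the published
  per-organ mean ± SD (e.g. 96 ± 66 µm² for *Betula pendula* midribs);
  disks are placed without overlap by rejection sampling, with a minimum
  edge-to-edge clearance of 2 µm standing in for the shared cell walls that
  separate real lumina (and keeping rasterised disks from fusing).
* **Per-conduit embolism** — each conduit draws an air-seeding threshold
  from a logistic distribution with location $b$ and scale $25/S$,
  independent of its area. A conduit is embolized at $\Psi$ iff
  $\Psi \le$ threshold, so the *expected* conductance-weighted PLC equals
  the target sigmoid exactly. Whether wide conduits embolize earlier is an
  open biological question; independence is the unbiased default, not a
  claim.
* **Images** — 8-bit frames at 0.65 µm/px (full frames 2615 px ≈ 1.7 mm
  field of view; simulations use smaller frames). Background renders at
  grey level 120, water-filled lumina 140, gas-filled lumina 40, walls 170,
  plus additive Gaussian noise (SD 5 by default).
* **Centrifuge runs** — branch vulnerability data mimic the cavitron
  protocol: pressure starts at −0.58 MPa and steps down until the noiseless
  curve reaches at least 90% PLC; observed PLC adds Gaussian noise (SD 2)
  and is clamped to [0, 100].
* **Trait tables** — per-replicate anatomical trait values are Gaussian
  around the published cell means, truncated at zero (and to [0, 1] for the
  aperture fraction).

What the generator does **not** emulate: reconstruction artefacts, phase
fringes, touching or elliptical lumina, partial volume effects, fibres and
parenchyma that could be mistaken for conduits, or axial structure. Passing
tests therefore demonstrate the correctness of the measurement chain on
idealised cross-sections, not robustness to every pathology of real
reconstructions.

## A worked scan pair

```{r scanpair}
pop <- sample_conduit_population(30, area_mean_um2 = 96, area_sd_um2 = 66,
                                 field_um = 150, seed = 5)
pop <- assign_embolism_thresholds(pop, b_MPa = -2.87, S = 40, seed = 6)
pair <- render_scan_pair(pop, psi_MPa = -3, field_render_params(150), seed = 7)
pair
measure_scan_pair(pair)
```

`measure_scan_pair()` segments both images (threshold 80 by default, between
the gas grey level and the background), pools areas with
`summarize_scan_pair()` — totals only, no conduit-by-conduit matching — and
returns the theoretical PLC.

## A full campaign and its vulnerability curve

```{r campaign}
obs <- simulate_vein_campaign(n_scans = 16, b_MPa = -2.87, S = 40,
                              psi_range = c(-0.5, -5.1), n_conduits = 50,
                              field_um = 190, seed = 1)
fit <- fit_vulnerability_curve(obs, label = "B. pendula midrib (synthetic)")
fit
autoplot(fit)
```

`tidy()` and `glance()` give the broom-style views, and
`compare_by_ci_overlap()` applies the study's decision rule: a difference in
P50 (or slope) between two organs is significant iff the two 95% confidence
intervals do not overlap.

## Design choices and numerical notes

**Segmentation.** Pixels below the threshold are foreground; 8-connected
components of at least 4 µm² (≈ 9 px; far below any plausible tracheid
lumen) are reported with pixel-count area and centroid, ordered row-major.
Otsu's method is the automatic threshold, but the pipeline defaults to the
fixed value 80: on a pre-cut image of a barely-embolized leaf the dark class
can vanish, and a bimodal split of background against water-filled lumina
would then call functional conduits embolized. Coordinates are 0-based
pixel indices; physical positions are pixel centres times the pixel size.
No hole filling or watershed splitting is applied (generator disks are
separated by construction).

**Fitting.** Bounded Levenberg–Marquardt least squares on the sigmoid as-is
(no logit transform, no weighting), with $S \in (0, 500]$,
$b \in [\min\Psi - 5, 0]$. Starting values: $b_0$ where linearly
interpolated PLC crosses 50 (fallback: median $\Psi$); $S_0$ from the slope
of the logit-linearised data (fallback 30). A fit whose parameters land on
a bound — e.g. all observations equal — is returned with
`converged = FALSE`, never silently. Noise-free data are recovered to
$10^{-6}$.

**Uncertainty.** Confidence intervals are Wald-type with the $t_{n-2}$
quantile. PLC scatter is strongly heteroscedastic — saturated tails vary
far less than the transition region, which carries nearly all information
about $b$ — so the default covariance is the HC3
heteroscedasticity-consistent (sandwich) estimator on the nonlinear
Jacobian; under binomial-like per-scan noise the classical homoscedastic
errors cover the truth in only ~60% of replicates at steep slopes, while
HC3 restores 92–96% empirical coverage. `se = "classical"` reproduces the
textbook errors, and `vc_bootstrap_ci()` offers seeded case-resampling
percentile intervals as a cross-check. Confidence bands in `autoplot()` are
pointwise Wald bands via the delta method.

**Campaign design.** Scans are spread evenly from −0.5 MPa down to the
potential where the expected curve reaches ≈ 97% PLC
($b - 3.5\cdot 25/S$), capped at the −9.5 MPa bench-drying limit. This
mirrors how vulnerability campaigns are actually run — the centrifuge
protocol stops once PLC exceeds 90% — and avoids spending most of a steep
species' 16–26 scans on saturated points that carry no information about
$b$. Per-species cross-sections use 50/35/40 conduits (*B. pendula*,
*L. nobilis*, *L. tulipifera*) in frames of roughly 190/220/210 µm:
larger-conduit species pack fewer conduits per bundle, and these sizes keep
the simulation studies (hundreds of full campaigns) tractable.

**Slopes.** Published slopes exist only for the *L. nobilis* leaf curves
(14.76 midrib, 7.75 second/third-order veins); the remaining presets use
40 %/MPa for the microCT leaf curves of the temperate species and
60 %/MPa (30 for *L. nobilis*) for centrifuge branches, consistent with the
very tight branch P50 standard errors (0.01–0.02 MPa) of those curves.

**Branch reporting.** Centrifuge P50 is reported as the mean of per-branch
fits (each branch segment yields its own curve), with a $t$-based interval
across branches; a pooled fit over all branch observations is available by
simply fitting the combined table.

**Anatomy statistics.** The aperture fraction is the mean of per-pit ratios
(the ratio of mean areas is a different number, and only the per-pit mean
reproduces the published species values). Membrane thickness is the mean of
exactly three measurements per membrane. Organ contrasts run Shapiro–Wilk
per group and Levene's test (centred on means) first, then Student's
pooled-variance t-test if Levene's p > α and Welch's otherwise — the
pretest implies a conditional branch, and the branch taken is always
reported. Spearman correlations get a permutation p-value (exact below
n = 9, seeded Monte-Carlo above) alongside the asymptotic one, because
published small-n correlation p-values rarely state their method. α is
fixed at 0.05 with no multiplicity correction (an optional Holm adjustment
can be applied to the output column with `p.adjust`).

One published number is deliberately not asserted anywhere: the
T_PM-versus-P50 correlation of r = −0.92 (n = 6). Recomputing either
Spearman's or Pearson's coefficient from the six printed organ means does
not reproduce it; the package's test suite records the sign agreement and
the discrepancy instead of forcing the value.

## Problem sizes used by the checks

The simulation studies in the test suite use the preset sample sizes
(16/26/24 leaves; 13/21/20 vein scans; 6/4/4 branches), 200 replicate
campaigns per species for parameter recovery, 50 seeded renders for
segmentation robustness, and 2000 null simulations for the type-I error of
the trait-comparison procedure — sizes chosen so the whole suite runs on a
laptop-class single core in minutes while keeping Monte-Carlo error well
inside the asserted bands.

## Known limitations

* The generator's independence of embolism threshold and conduit size is a
  modelling choice; diameter-correlated embolism would change the shape of
  realised PLC noise (not its expectation under the conductance weighting
  used here).
* Segmentation assumes well-separated, roughly circular lumina; real
  cross-sections with touching vessels would need the watershed-style
  splitting this package intentionally omits.
* Absolute conductances are in printed-constant units; only PLC ratios and
  parameters derived from them are meaningful.
* Vessels and tracheids are not distinguished; every dark lumen above the
  size filter counts as a conduit.
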