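---
title: "Simulating multi-reader reproducibility of partition-model Y-90 dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating multi-reader reproducibility of partition-model Y-90 dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Multicompartment (partition-model) dosimetry for yttrium-90 radioembolization
splits the injected activity between tumour and normal liver tissue using the
pre-treatment ⁹⁹ᵐTc-MAA SPECT count distribution, and reports the tumour
absorbed dose (TAD) and normal-tissue absorbed dose (NTAD). Its clinical value
depends on how reproducibly different physicians arrive at the same numbers.
Two segmentation practices dominate: contouring compartments on anatomic
CT/MRI, and selecting voxels above a percent-of-maximum count threshold within
a user-defined box on the SPECT itself. `rrdose` simulates a round-robin
study of this workflow — many reviewers independently segmenting the same
patients under both methods, twice for a subset — and evaluates agreement with
the statistics used in multi-reader quantitative-imaging studies.

Everything is driven by synthetic digital phantoms, so every stage is testable
without any clinical data, and ground truth (true volumes, true uptake, a
known fold-reproducibility for the estimator checks) is available by
construction.

## The dosimetry model

For a segmentation with perfused volume mass $m_P$ (kg), the administered
activity prescribing a mean dose $D_P$ (120 Gy by default) to the perfused
volume is

$$A = \frac{D_P\, m_P}{F},$$

with $F$ the dose factor in Gy·kg/GBq. With $f_t$ the fraction of perfused
counts inside the perfused tumour compartment (total tumour intersected with
the perfused volume) and $m_t$, $m_n$ the tumour and perfused-normal masses,

$$\mathrm{TAD} = \frac{F A f_t}{m_t}, \qquad
  \mathrm{NTAD} = \frac{F A (1-f_t)}{m_n}.$$

Because $m_P = m_t + m_n$ exactly (the compartments partition the perfused
volume) the mass-weighted mean of TAD and NTAD over the perfused volume equals
$D_P$ identically; the package asserts this conservation for every simulated
cell at relative tolerance $10^{-9}$. Whole-liver compartments use count
shares of the whole-liver counts and whole-liver masses; counts outside the
whole liver are ignored. Count normalisation for the perfused compartments is
to counts *within the perfused volume* (the alternative — field-of-view
counts — is not used; the convention is recorded in each `dose_report`).

Constants: $F = 50$ Gy·kg/GBq, the rounded clinical convention for ⁹⁰Y under
complete local absorption (the MIRD value 49.67 is available through
`dose_constants()`), and a uniform soft-tissue density of 1.03 g/cm³.
Voxel-level dose kernels are deliberately out of scope: the endpoints are
compartment mean doses.

## The phantom and acquisition model

A patient is an axis-aligned ellipsoidal liver (defaults around 1.2–1.7 L)
containing a unilobar perfused territory (liver clipped by a half-space,
40–70% of the liver) and 1–5 spherical tumours, a single tumour being most
common and the largest lesion at least 3 cm in diameter. Tumours may carry a
central necrotic core (zero uptake). Relative uptake is 1 in perfused normal
tissue, TNR (tumour-to-normal ratio, log-normal around 5) in viable tumour,
and 0 elsewhere.

The SPECT-like count map is produced by: rigid misregistration of the uptake
map (trilinear interpolation; per-axis shifts ~ N(0, 2 mm), emulating
registration error between SPECT and the anatomic frame), isotropic Gaussian
point-spread blur (FWHM 12 mm, typical of clinical SPECT), normalisation to a
total count budget (2 × 10⁶), and independent Poisson counts per voxel. An
expected-counts mode skips the Poisson draw so oracle tests can be exact. The
blur kernel is column-normalised, so it conserves total counts exactly,
boundary included. The grid is 96³ voxels at 2 mm isotropic — large enough to
resolve ≥ 1 cm tumours, small enough that the full default study runs in a
couple of minutes. What the generator does *not* model: attenuation, scatter,
collimator response, reconstruction artefacts, non-rigid deformation, and
anatomic-image appearance. Passing tests therefore demonstrate the behaviour
of the segmentation-and-statistics pipeline under controlled, idealised
imaging, not performance on clinical images.

## The reviewer model

Reviewer behaviour is the quantity under study, and no distributional
description of real reviewers is available; the generative model is an
explicit stand-in with hyperpriors chosen once:

* **Anatomic contouring**: each structure boundary is displaced by a signed
  margin drawn per structure and assessment from N(0, σ_contour), realised as
  Euclidean-distance-transform dilation or erosion. A global signed margin
  (rather than per-voxel noise) captures systematic over-/under-contouring and
  keeps an analytic oracle (a +2 mm margin on a 10 mm sphere scales its volume
  by (12/10)³). Per-reviewer σ_contour is half-normal with scale 2 mm.
* **Count-threshold segmentation**: the whole liver is taken from the
  reviewer's anatomic delineation; the perfused territory uses a low
  percent-of-maximum threshold (centre 0.05) over a box enclosing all counts;
  each tumour a high threshold (centre 0.40) in a box around the lesion padded
  by the reviewer's box margin (≈ 10 ± 3 mm). Realised fractions are
  *multiplicative*: centre × exp(bias + jitter), with a per-reviewer log-scale
  bias ~ N(0, 0.20) and per-assessment jitter with half-normal scale 0.20.
  A threshold is a positive fraction, so perturbing it on the log scale gives
  comparable relative spread at the 0.05 and 0.40 centres; an additive
  perturbation large enough to matter at 0.40 overwhelms the 0.05 centre
  entirely and inverts the clinically observed regime, where small tumour
  structures are by far the least reproducible. With these defaults the
  simulated magnitudes land loosely in the reported clinical ranges (e.g.
  count-threshold perfused-normal volume RDC ≈ 1.6, tumour-dose RDC ≈ 1.7,
  with heavy-tailed tumour-volume RDC), and all qualitative orderings —
  reproducibility degrading with compartment size, anatomic beating
  count-threshold on tumour endpoints — emerge from the mechanism rather
  than from fitting.

Thresholding is inclusive (≥) against the box maximum, ties included, with no
connected-component post-filtering (none is described for the clinical tool).
The target lesion is the largest tumour by volume, ties broken by lowest
index. A tumour whose box holds no counts, or whose mask comes back empty, is
recorded as *missing* and flows into the exclusion ledger; statistics use only
surviving records, with reduced n reported.

## Agreement statistics

All reproducibility analysis is on the natural log scale (the base cancels in
the exp ∘ estimate ∘ ln round trip). For one endpoint and method, the first
assessments follow a crossed random-effects model

$$\ln y_{is} = \mu + p_i + r_s + \varepsilon_{is},$$

with patient, reviewer and residual components estimated by REML (closed-form
expected-mean-square solutions on complete balanced tables, where they
coincide with REML at interior optima; a profiled REML criterion via the
Woodbury identity on incomplete tables, validated against `lme4`). Negative
component estimates are truncated at zero. The reproducibility coefficient is

$$\mathrm{RDC} = \exp\!\left(1.96\sqrt{2}\sqrt{\sigma^2_{r} + \sigma^2_{\varepsilon}}\right),$$

the maximum fold-ratio between two reviewers' measurements expected in 95% of
cases. Repeat assessments never enter the inter-observer fit.

**Confidence interval.** The 95% CI is a seeded nonparametric percentile
bootstrap resampling *both* patients and reviewers (B = 2000 by default).
A patient-only bootstrap was evaluated first and rejected: holding the
reviewer panel fixed, the bootstrap distribution of the reviewer variance
component collapses around its sample value, and measured coverage of a known
true fold-RDC fell to 46% with an even reviewer/residual variance split and
92.7% even with no reviewer component; the two-way bootstrap reaches nominal
95% coverage when reproducibility variance is residual-dominated. Both
schemes undercover when a large systematic reviewer offset component meets
only eight reviewer levels — a structural limit of resampling so few levels,
flagged here rather than hidden. For the same reason the synthetic
measurement-table generator defaults place the reproducibility variance
(log-SD 0.25, true fold-RDC 2.0) in the residual: per-case idiosyncratic
disagreement, not constant reviewer offsets, dominates segmentation
variability; a reviewer component is a parameter for sensitivity analyses.

Grades summarise the CI upper bound: grade 1 below 1.5-fold, 2 in [1.5, 2),
3 in [2, 3), 4 at or above 3 — lower tier edges inclusive.

Supporting statistics, all per the multi-reader conventions: per-patient
CV% (sample SD over mean) and MAPE (mean over reviewers of
100·|y − ȳ|/ȳ); outliers flagged separately per assessment outside
Tukey-hinge quartile fences at 3 × IQR (hinges are reproducible by hand at
n = 8: Q_L = (x₍₂₎ + x₍₃₎)/2); log-scale Bland–Altman between methods with
bias and limits of agreement back-transformed to percent differences; and
intra-observer variability as the raw-scale repeatability coefficient
IOV = 1.96·√2·σ_w with σ²_w = Σd²/(2N) over assessment pairs — this estimator
is a re-specification (the original supplementary definition is not
available) and is isolated behind one function so it can be swapped.

## Numerical and design choices

* **Seeding** is hierarchical: one master seed derives per-patient,
  per-reviewer, per-assessment and per-stage substreams (`derive_seed()`), so
  any cell of the study is reproducible in isolation and the whole study is
  deterministic end to end.
* **Geometry conventions**: voxel indices are 0-based, boxes half-open in
  index space, world coordinates in mm at voxel centres. Misregistration is
  applied to the count map; the anatomy is the fixed frame.
* **Degenerate inputs**: an all-zero uptake map, an all-zero threshold box,
  a non-positive perfused mass, and fewer than two reviewers or patients are
  errors; an annihilated structure is a missing compartment (marker, never a
  zero volume); a zero-variance table yields RDC exactly 1 with CI [1, 1].
* **Bootstrap guard**: the percentile interval is widened, if necessary, to
  contain the point estimate, keeping the invariant ci_low ≤ RDC ≤ ci_high.
* **Problem sizes** used by the test-suite checks were chosen to keep the
  whole suite at desk scale: the full default study (20 × 8, both methods,
  ~4.4 × 10⁵ dosimetry cells of 96³ voxels each collapsing to 480 dose
  reports), 500 replicate tables for parameter recovery, 1000 replicate
  studies at B = 500 for CI coverage.
* **Both methods share the realised phantom and count map** per patient, so
  method comparisons are paired.

## Known limitations

* The phantom is geometrically idealised (ellipsoids, spheres, uniform
  uptake); real tumour heterogeneity and infiltrative margins would add
  variability the simulator does not produce.
* The reviewer model has no learning effects, no inter-site scanner
  differences and no anatomic-modality split (CT vs MRI are one "anatomic"
  method here).
* RDC magnitudes for tumour endpoints are heavy-tailed and seed-sensitive at
  n = 20 patients; orderings between compartments and methods are stable, and
  only orderings are asserted.
* Bootstrap CIs with eight reviewers undercover in the presence of large
  systematic reviewer offsets (see above).
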