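---
title: "Quantifying cerebral hypometabolism with voxel-wise asymmetry indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cerebral hypometabolism with voxel-wise asymmetry indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aindex)
```

## The model

Unilateral ischemic cerebrovascular disease depresses glucose metabolism in
the affected hemisphere, both inside the infarct and in structurally intact
peri-infarct and remote (diaschisis) tissue. Because absolute FDG uptake
varies between subjects and scans, the quantification is built on two
within-scan normalizations:

1. **SUVR**: every voxel is divided by the mean activity in a reference
   region assumed metabolically spared — here the pons
   (`suvrNormalize()`). The reference mean of the output is exactly 1.
2. **Left–right asymmetry**: each affected-side (ipsilateral) voxel is
   compared with its mirror partner on the unaffected (contralateral)
   side. With values $S_i$ and $S_c$,
   $$AI_1 = 100\,\frac{S_c - S_i}{S_c}, \qquad
     AI_2 = 100\,\frac{2\,(S_c - S_i)}{S_c + S_i}.$$

Both indices are invariant to global scaling of the volume, so the SUVR
step does not change them; it matters only for interpretation and for any
absolute-value analyses downstream. Writing $a_1, a_2$ for the indices as
fractions, the two are linked voxel-wise by
$$a_2 = \frac{2 a_1}{2 - a_1},$$
implemented as `ai2OfAi1()` and used as an analytic oracle in the tests.
Since $a_2 \ge a_1$ wherever both are defined (with equality only at 0),
the AI2 method *always* measures at least as much hypometabolic volume as
AI1 at any common threshold; a threshold $t$ on AI2 is exactly equivalent
to the smaller threshold $2t/(2+t)$ on AI1 (9.5238% for the standard
$t = 10\%$).

**Orientation.** We define ipsilateral = affected hemisphere and
contralateral = unaffected hemisphere. Under this orientation a
hypometabolic affected-side voxel has positive AI, and the volume of
decreased metabolism is the set of valid affected-side voxels with
AI > 10% (strict inequality; `hypometabolicMask()`). The opposite
orientation would make every hypometabolic voxel negative and the
threshold rule vacuous, which is inconsistent with positive hypometabolic
volumes being the object of study. Negative AI (affected-side
hypermetabolism) is retained in the map but never counted.

**Infarct exclusion.** The infarct core is delineated separately (here:
supplied as a mask) and removed from the analysis on *both* sides: a voxel
is excluded if it or its mirror partner is infarcted (`exclusionMask()`),
so necrotic tissue neither contributes asymmetry nor serves as a reference
for its mirror partner.

**Validity.** A voxel enters the analysis only if it lies on the affected
side, is not excluded, both paired values are finite and the method's
denominator is positive ($S_c > 0$ for AI1, $S_c + S_i > 0$ for AI2). The
two methods may therefore have slightly different evaluable sets in noisy
data; each method's percentage uses its own evaluable denominator so both
remain internally consistent ratios.

## The mirroring contract

The paper-level workflow registers each PET to the subject's anatomy and
an atlas; this package instead assumes its inputs are already resampled to
a grid whose midsagittal plane is the centre of a declared mirror axis.
Left–right correspondence is then index reversal along that axis
(`mirror()`), an involution by construction. For an even-sized mirror axis
the reflection plane lies between the two central slices and no voxel is
its own mirror; for an odd-sized axis the central slice maps to itself and
is treated as midline, belonging to neither hemisphere and excluded from
hemispheric quantification. This keeps the pipeline self-contained and its
geometry exactly testable; the cost is that spatial normalization quality
becomes the caller's responsibility, as it is for any template-space
voxel-wise method.

## Regional quantification

A label atlas with a (label → region, lobe, hemisphere) lookup table
defines the reporting regions: the frontal, temporal, parietal and
occipital lobes and the whole affected hemisphere (the union of all
affected-side parcels; midline structures such as the pons are never
included, and the lobes need not sum to the hemisphere for richer
atlases). For each region,

- evaluable set = affected-side region voxels that are valid (exclusion
  and denominator guards already applied),
- hypometabolic volume = `count(hypo ∩ evaluable) × voxel volume [mL]`,
- percentage = `100 · count(hypo ∩ evaluable) / count(evaluable)`.

A region with an empty evaluable set is reported as `NA`, not 0 — "no
measurable tissue" and "no hypometabolism" are different findings.

## Partial-volume correction

PET resolution blurs the lesion boundary. `vanCittert()` implements the
classic additive Van-Cittert deconvolution
$f_0 = g,\; f_{k+1} = f_k + \alpha\,(g - h \otimes f_k)$ with a Gaussian
kernel $h$, optional non-negativity clamping, and defaults of 10
iterations, $\alpha = 1$ and a 3 mm kernel (the scale of a clinical
reconstruction filter). The kernel width, iteration count and relaxation
are explicit parameters, written into every run manifest, because the
method is conventionally named without them and results depend on them.
Van-Cittert amplifies high-frequency noise (there is no regularization),
so on noisy data it should be applied deliberately; the cohort drivers
leave it off unless requested. Region-based or anatomically guided PVC is
out of scope.

The Gaussian blur itself is a separable per-axis convolution with a
truncated (4 SD), row-renormalized kernel: constant images are preserved
exactly at the edges and the operator commutes with `mirror()`, which the
phantom tests rely on.

## The synthetic phantom

`makeSubject()` builds an ellipsoidal brain (semi-axes 0.44 of each grid
extent) partitioned into lobar octants per hemisphere by the
anterior–posterior and superior–inferior midplanes, plus a midline pons
sphere. A spherical infarct core (radius default 5 mm, uptake scaled by
`1 − fInfarct`, default reduction 80%) sits inside a spherical
hypometabolic shell (radius default 12 mm, uptake scaled by `1 − f`),
entirely within one hemisphere. The volume is then blurred with a Gaussian
PSF and degraded with additive Gaussian noise, both seeded; ground truth
(masks, shell volume, `burden = shell volume × f`) reflects the pre-blur
geometry. Defaults: 48 × 56 × 48 voxels of 3 mm — a head-sized desk-scale
grid — with lobar baselines 9–10.5 kBq/mL against a pons baseline of 8.

The simulated cohort (`cohortSpec()`, default n = 70) draws the shell
reduction `f` uniformly from [0.12, 0.4] — so shell voxels exceed the 10%
rule by construction while blur and noise can push boundary voxels either
way — shell radii from [9, 15] mm, infarct radii from [3.5, 6] mm, with a
3 mm PSF and noise SD 0.2 (2% of baseline). Clinical scores follow a noisy
monotone link, `NIHSS = round(2.5 · burden + ε)` clipped to 0–42 and
`mRS = round(burden + ε′)` clipped to 0–6 (ε SD 1.5, ε′ SD 0.5), chosen so
typical burdens of 0.3–5.6 mL span the moderate clinical range.
`simulateFollowup()` rebuilds each subject with
`f_post = (1 − g) · f_pre`; `g` may vary per subject and may be negative
to model deterioration, so improved/worsened subgroups can be constructed
exactly.

What the phantom does **not** emulate: irregular lesion shapes, cortical
folding, Poisson/reconstruction noise, registration error and atlas
mislabelling. Volumetry depends only on membership counts, so spherical
geometry costs no generality for the properties tested; but passing tests
on phantoms validate the *computational* pipeline, not the upstream
registration and delineation a clinical deployment would also need.

## Statistics

`pairedT()`, `blandAltman()` and `spearmanCor()` are written from their
defining formulas because their degenerate-case behaviour is part of the
package contract: a zero-variance difference vector yields a flagged
degenerate p (1 if the mean difference is 0, else 0) rather than an error;
Spearman's p uses full permutation enumeration for n ≤ 9 without ties and
the t approximation ($t = \rho\sqrt{(n-2)/(1-\rho^2)}$, n − 2 df)
otherwise, the standard practice when the method is unstated. Base-R
`t.test()` and `cor.test()` serve as independent cross-checks in the test
suite. No multiple-testing correction is applied across regions or scales,
matching per-test reporting conventions for this analysis. Follow-up
change uses the pre − post sign convention, so positive change means
reduced hypometabolic burden, and all reported p-values are two-sided.

## Numerical choices and edge cases

- Threshold comparisons are strict (`AI > 10`), a measure-zero distinction
  for continuous data made explicit for reproducibility.
- Seeds are mandatory for every stochastic constructor; cohort generation
  is a pure function of (spec, seed), and per-subject seeds are drawn from
  the master seed so subjects are independent but reproducible.
- Noise-free, blur-free phantoms are recovered *exactly*: the
  hypometabolic mask equals the shell minus the exclusion, voxel for
  voxel, and volumes match the brute-force membership count times the
  voxel volume. With noise, recovery error shrinks monotonically with the
  noise SD (asserted over a 3-level ladder in the tests).
- For the score-link recovery check the cohort uses a constant `f`: the
  noise-free score is then strictly monotone in the *measured* volume, so
  Spearman's rho must approach 1 as link noise vanishes. With `f` drawn
  from a range, burden and measured volume are decoupled by design and the
  correlation is positive but bounded away from 1.
- The cohort driver quarantines per-subject failures (grid mismatch,
  degenerate reference) with a warning instead of aborting the cohort, and
  writes every effective parameter to a JSON run manifest.

## Problem sizes

The default test-suite and acceptance problem sizes are 24³–48·56·48-voxel
grids and cohorts of up to 70 subjects; the full 70-subject simulate +
quantify + report cycle completes in seconds on one CPU, and the analytic
identity checks scan 10⁶ voxel pairs.
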