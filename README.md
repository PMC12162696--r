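# aindex

Voxel-wise asymmetry-index quantification of cerebral hypometabolism on
FDG-PET SUVR volumes, for unilateral ischemic cerebrovascular disease
(internal carotid / middle cerebral artery steno-occlusion).

## The problem and the method

In unilateral stroke, metabolism in the affected hemisphere is depressed
relative to its mirror region on the unaffected side. With PET activity
converted to the standardized uptake value ratio (SUVR; voxel activity
divided by the mean activity in a pons reference region), the left–right
asymmetry at each affected-side voxel with value `S_ipsi` and mirror-partner
value `S_contra` can be written two ways:

    AI1 = 100 * (S_contra − S_ipsi) / S_contra
    AI2 = 100 * 2 (S_contra − S_ipsi) / (S_contra + S_ipsi)

AI1 normalizes by the unaffected (contralateral) value; AI2 by the bilateral
mean, which is smaller wherever the affected side is hypometabolic, so AI2
amplifies the same voxel pair: wherever both are defined,
`AI2 = 2·AI1 / (2 − AI1)` (as fractions), hence `AI2 ≥ AI1` at every voxel
and an AI2 > 10% rule is equivalent to AI1 > 9.52%. The *hypometabolic
volume* is the total volume of affected-side voxels with AI above 10%,
after removing every infarcted voxel **and** its mirror partner; the
*percentage* refers this volume to the evaluable regional volume.

The package provides:

- S4 containers (`BrainVolume`, `BrainMask`, `BrainAtlas`, `AsymmetryMap`)
  with NIfTI/JSON/CSV I/O and an explicit mirror-axis contract;
- preprocessing: Van-Cittert partial-volume correction and pons-referenced
  SUVR normalization;
- the asymmetry core: `exclusionMask()`, `aiMap()`, `hypometabolicMask()`,
  `regionalQuantify()` (frontal/temporal/parietal/occipital lobes and the
  affected hemisphere);
- a synthetic phantom generator with geometric ground truth
  (`phantomSpec()`, `makeSubject()`, `simulateCohort()`,
  `simulateFollowup()`), including clinical NIHSS/mRS scores linked
  monotonically to the hypometabolic burden;
- cohort statistics: paired t comparison of the two AI methods,
  Bland–Altman agreement, Spearman correlation with clinical scores, and
  paired follow-up change (`cohortReport()`, `followupChange()`);
- drivers `runSubject()` / `runCohort()` / `runPipeline()` (YAML config,
  CSV + JSON-manifest outputs).

## Worked example

Simulate one subject with a 25% peri-infarct uptake reduction, 3 mm PSF
blur and additive noise, then quantify hypometabolism with both methods:

```r
library(aindex)
s <- makeSubject(phantomSpec(f = 0.25, psfSigma = 3, noiseSd = 0.2, seed = 42))
out <- runSubject(s$volume, s$atlas, s$infarct, s$pons, affectedSide = "L")
print(out, digits = 4)
```

```
       region method volume_ml percentage evaluable_ml
1          FL    AI1     6.912    4.45915        155.0
2          TL    AI1     0.135    0.08684        155.5
3          PL    AI1     0.675    0.43418        155.5
4          OL    AI1     0.405    0.26302        154.0
5  hemisphere    AI1     8.127    1.31098        619.9
6          FL    AI2     7.074    4.56366        155.0
7          TL    AI2     0.297    0.19104        155.5
8          PL    AI2     0.756    0.48628        155.5
9          OL    AI2     0.567    0.36823        154.0
10 hemisphere    AI2     8.694    1.40244        619.9
```

The lesion's true shell volume net of the infarct-pair exclusion is
6.696 mL; the PSF blur spreads the deficit slightly beyond the shell, and
AI2 recovers a larger volume than AI1 in every region — the systematic
method difference the statistics layer quantifies. On a simulated
70-subject cohort (`simulateCohort(cohortSpec(seed = 1))`) the paired
difference is positive for all 70 subjects (mean 0.71 mL in the affected
hemisphere, paired t p ≈ 1.9e-48).

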