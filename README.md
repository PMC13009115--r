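# ewimap

Activation mapping for cardiac **electromechanical wave imaging (EWI)**
and its comparison against **electrocardiographic imaging (ECGI)**, as an
R package with a fully synthetic, ground-truth-driven test bed.

EWI infers the cardiac activation sequence from high-frame-rate
ultrasound (2000 fps): at every myocardial site, the incremental axial
strain trace switches from positive (diastolic lengthening) to negative
(systolic shortening) at the onset of local contraction, so the first
**downward zero crossing (ZC)** of the strain curve — referenced to QRS
onset or a pacing spike — serves as the local electromechanical
activation time. Scattered ZC annotations are interpolated over the
segmented myocardium (Delaunay-based cubic interpolation), views are
co-registered on the surface ECG, and the site of earliest activation
gives the arrhythmia's site of origin (SoO), both anatomically (on a
biventricular 24-segment model) and transmurally (endo / mid / epi by
wall-depth tercile). ECGI reconstructs epicardial unipolar electrograms
sampled at 1000 Hz (100 Hz low-pass) and annotates local activation at
the **maximum negative dV/dt**; QS-vs-rS morphology and slew rate serve
as surrogates for transmural depth. Comparing the two on jointly covered
segments measures the electromechanical delay,
`delta = EWI_AT − ECGI_AT` (positive when ECGI precedes EWI).

The package is aimed at researchers developing or validating
non-invasive ventricular-arrhythmia mapping pipelines: every stage —
phantom generation (masks, geodesic wavefronts, strain movies, RF
frames, electrograms, paired cohorts), RF displacement/strain
estimation, ZC detection, isochrone interpolation, SoO localization,
electrogram analysis, bullseye extraction, delay statistics and
localization scoring — is an exported, tested function.

## Worked example

```r
library(ewimap)

## one noiseless echocardiographic view: phantom -> strain movie ->
## zero crossings -> isochrones -> site of origin
m   <- buildMask(viewGeometry(depthMax = 60), rEndo = 30, rEpi = 40,
                 spacing = 0.8)
f   <- simulateActivation(m, sourceSpec("S2", "mid", originTime = 10,
                                        cv = 0.8))
mov <- synthesizeStrain(f, delay = 0, durationMs = 300)
mv  <- mapView(mov, n = 300, seed = 1)
localizeSoO(registerViews(list(list(map = mv$map, ecg = mv$ecg))))
#> SoOEstimate: segment S2, layer mid, earliest 11 ms (view 4ch)
```

The phantom's focal source sat in segment S2, mid-wall, firing 10 ms
after QRS onset; the pipeline recovers segment and layer, and the 11 ms
earliest time reflects the source onset plus one pixel of wavefront
travel to the nearest sampled site.

```r
## a paired 33-subject cohort under the all-patients delay model
## (Gaussian, mean 45 ms, SD 28 ms)
cohort <- generateCohort(cohortSpec(33, seed = 1), emd = emdModel("all"))
emd    <- cohortEMDTable(cohort)
c(mean(emd$delta), sd(emd$delta), mean(emd$delta > 0))
#> 45.6  28.4  0.936
```

The per-segment activation-time differences recover the generating
delay model — ECGI precedes EWI on 94% of segments — because the ZC
marks mechanical onset while max −dV/dt marks electrical
depolarization. With per-subgroup delay models
(`generateCohort(cohortSpec(33, seed = 1))`) the subgroup table and its
ANOVA separate the groups:

```r
sa <- subgroupAnalysis(cohortEMDTable(generateCohort(cohortSpec(33, seed = 1))))
subset(sa$cells, row == "Global")
#>    row      column     mean       sd   n
#> Global         All 44.73103 28.27208 594
#> Global      LGE+ve 51.61861 28.95602 360
#> Global LVSD&LGE-ve 39.83271 26.72274  72
#> Global      normal 31.60234 21.66337 162
sa$anovaP[["Global"]]
#> 4.79e-14
```

A thin command-line wrapper (`inst/scripts/ewi-pipeline.R`) exposes the
pipeline stages (`simulate`, `strain`, `map`, `ecgi`, `compare`,
`report`) over YAML/JSON configurations; outputs are HDF5 strain
containers, CSV tables and a manifest with file hashes for
reproducibility.

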