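# octasym

Intereye asymmetry analysis of OCTA en-face angiograms.

`octasym` is for researchers quantifying the retinal microvasculature on
en-face optical coherence tomography angiography (OCTA) images and asking
whether — and where — the two eyes of the same patient differ, for example
across diabetic retinopathy (DR) stages. It implements the measurement
stack and the paired-eye statistics as one tested pipeline:

* **Vessel segmentation** by global thresholding at
  `threshold = mean + std_coeff · sd` over the image's pixel values
  (`std_coeff = 0.5` for all vessels, `1.3` for the big arcade vessels
  only), with big-vessel exclusion so density reflects the
  microcirculation.
* **Vessel density (VD)** — the fraction of measured area occupied by
  vessel pixels — per ETDRS sector (central 1 mm, inner ring 1–3 mm,
  outer ring 3–6 mm, total 6-mm disc) on a grid centered on the FAZ.
* **Fractal dimension (FD)** by box counting: FD = −slope of the OLS fit
  of log N(s) vs log s over a dyadic box ladder.
* **FAZ metrics** from a traced boundary polygon: area (shoelace, mm²),
  perimeter (mm), and circularity `FAZC = 4π·Area / Perimeter²` (1 for a
  perfect circle).
* **Intereye asymmetry**: per patient and metric, the absolute
  difference `δ_abs = |R − L|` and the asymmetry index
  `AI = |R − L| / ((R + L)/2) × 100`.
* **Cohort statistics**: Kruskal-Wallis across DR stages, Wilcoxon
  signed-rank for inner-vs-outer ring, and linear mixed models
  `response ~ stage + side + age + hba1c + sex + stage:side +
  (1 | patient)` (REML, Wald CIs, Satterthwaite F-tests) with the
  standard branching: stage contrasts vs "no DR" when the stage F-test is
  significant, per-stage left-vs-right contrasts when the interaction is.
* **Synthetic generators** for ground-truthed paired-eye angiograms and
  metrics-level cohorts, so every stage is testable without clinical data.

## Worked example

Generate a noise-free synthetic angiogram with a planted capillary
fraction of 0.25, run the measurement stack, and fit the cohort model on a
synthetic metrics cohort:

```r
library(octasym)

p    <- image_gen_params(capillary_fraction = 0.25, noise_sd = 0, seed = 7)
pair <- generate_angiogram_pair(p)

all_v <- binarize(pair$right, std_coeff = 0.5)
big   <- big_vessel_mask(pair$right, dilation_radius = 0)
am    <- analysis_mask(all_v, big, plexus = "SCP")
grid  <- build_grid(c(249.5, 249.5), p$pixel_pitch, p$image_size)

vessel_density(am$capillary_mask, am$excluded_area_mask, grid)
#> <sector_vd> total 0.2485, IR 0.2526, OR 0.2517 (central 0.1321)
fractal_dimension(am$capillary_mask)
#> <fractal_result> fd 1.7894 (R^2 0.9950), 6 box sizes [2..64]
faz_metrics(faz_trace(pair$truth_right$faz_polygon, p$pixel_pitch))
#> <faz_metrics> area 0.2857 mm^2, perimeter 2.042 mm, circularity 0.8608
```

The recovered total VD (0.2485) matches the planted fraction within the
pixel-quantization tolerance; the FD and FAZ values sit in the range
typical of superficial-plexus angiograms. Asymmetry of a metric between
fellow eyes:

```r
asymmetry(0.22, 0.20)
#>   delta_abs asymmetry_index
#> 1      0.02         9.52381
```

Cohort-level inference on a synthetic cohort with a planted −0.009
left-eye offset (34 patients per DR stage):

```r
co <- generate_metrics_cohort(cohort_gen_params(seed = 7))
m  <- fit_intereye_model(co)
m
#> Intereye linear mixed model for 'response' (340 eyes, 170 patients)
#>   side (left vs right, marginal): -0.009303 [-0.01113; -0.007475], p = 7.96e-19
#>   F-tests: stage p = 3.51e-05, stage:side p = 0.967
#>   variance components: patient 0.000274, residual 7.29e-05
```

The marginal side estimate recovers the planted offset; the interaction
F-test is quiet (none was planted), so `branch_and_contrast(m)` reports
the single overall side effect plus stage-vs-no-DR contrasts.

The full pipeline (segment → grid → metrics → pair eyes → statistics)
runs from a manifest of PNG images and FAZ polygon CSVs, or in synthetic
mode, via `run_pipeline(pipeline_config(...))`; a thin command-line
wrapper lives at `inst/cli/octa-intereye.R`.

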