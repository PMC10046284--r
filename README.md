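# dabquant

Objective scoring of DAB immunohistochemistry for biomarker triage.

When a candidate tumor biomarker is evaluated for applications such as
fluorescence-guided surgery (FGS), the question is not just "does the tumor
stain?" but "how much more strongly does the tumor stain than the healthy
tissue a surgeon would cut through?". `dabquant` answers this with an
objective, reproducible 5-step measurement of DAB (3,3′-diaminobenzidine)
chromogen staining on brightfield histology tiles:

1. **ROIs** — rasterize pathologist-annotated tumor and adjacent-healthy
   polygons (GeoJSON) to pixel masks;
2. **Color deconvolution** — convert RGB to optical density
   (`OD_c = −log10((I_c + ε)/(I0_c + ε))`) and unmix with the standard
   H-DAB stain matrix, keeping only the DAB channel
   (per pixel, `densities = OD · M⁻¹` with row-normalized stain matrix `M`);
3. **Grayscale** — re-render the DAB channel and collapse to monochrome
   (0–255);
4. **Invert** — so high pixel values mean high DAB density;
5. **Measure** — mean and SD of staining intensity inside each ROI, and the
   tumor-to-background ratio

   `TBR = mean tumor intensity / mean adjacent-healthy intensity`.

Cohort-level helpers aggregate samples to patients (unweighted means, TBR
recomputed from averaged means), summarize each biomarker, and run the
paired (tumor vs. adjacent healthy) and unpaired (with vs. without
preoperative therapy) t-tests, with broom-style `tidy()`/`glance()` methods.
A TBR ≥ 1.5 is the usual rule of thumb for an FGS-usable target.

Because clinical slide sets are rarely public, the package ships a seeded
**Beer–Lambert phantom generator**: synthetic H-DAB tiles with hematoxylin
counterstain everywhere, region-dependent DAB density with a calibrated
mid-frequency texture, Gaussian OD-space pixel noise, and white fat-vacuole
holes in the background (deliberately included in the measurements, as in
the assay it emulates). Three 17-case cohort presets (`TEM1`, `VEGFA`,
`PDGFRA`) encode published per-biomarker summary statistics as ground
truth, so the *entire* pipeline — image synthesis through cohort
statistics — is verifiable as a parameter-recovery exercise.

## Worked example

```r
library(dabquant)

res <- run_cohort_pipeline("TEM1", dir = tempfile(), seed = 42,
                           height = 256, width = 256, quiet = TRUE)

res$scores[1:4, c("sample_id", "tumor_mean", "tumor_sd", "bg_mean", "tbr")]
#>   sample_id   tumor_mean tumor_sd bg_mean   tbr
#> 1 TEM1_case01       40.3     21.7    38.0  1.06
#> 2 TEM1_case02       54.9     28.4    44.0  1.25
#> 3 TEM1_case03       40.1     22.1    36.4  1.10
#> 4 TEM1_case04       69.8     35.0    45.1  1.55

res$summary
#>   biomarker n_patients mean_tumor_intensity mean_within_roi_sd mean_tbr
#> 1 TEM1              17                 81.3               39.7     3.01

res$subgroup[, c("metric", "mean_preop", "mean_none", "p_value")]
#>   metric          mean_preop mean_none p_value
#> 1 tumor_intensity      85.2      74.1    0.438
#> 2 tbr                   3.46      2.19   0.100

paired_t(res$patients$tumor_mean, res$patients$bg_mean)
#> <ihc_ttest> paired: t = 6.4569, df = 16, p = 7.922e-06 (significant at alpha = 0.05)
```

Reading: per-slide rows give the inverted-grayscale mean DAB intensity in
the tumor and adjacent-healthy ROIs and their ratio; the cohort summary
shows this biomarker averaging a tumor intensity of ~81 with a ~3× contrast
over background; the subgroup table shows no significant effect of
preoperative therapy; the paired test confirms tumor staining exceeds
background across patients. Each of these numbers is recovered by
measurement from rendered pixels — the generator plants densities, not
intensities.

`plot_paired_intensities(res$patients)` draws the per-patient
tumor/background pairs (TBR < 1 cases in red),
`plot_biomarker_summary(res$summary)` the mean TBRs against the 1.5× line,
and `gradient_map()` renders a slide's DAB distribution through a
perceptually monotone colormap.

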