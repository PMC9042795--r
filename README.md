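# rnpgranules

Quantitative image analysis of RNP granules and biomolecular condensates in
fluorescence microscopy, with a seeded synthetic-microscopy generator so the
whole pipeline can be validated against known ground truth.

Ribonucleoprotein (RNP) granules — such as the *oskar* mRNA transport
granules of the *Drosophila* oocyte — are micron-and-below condensates whose
biology is read out through a small set of image-derived quantities: how big
and how round the granules are, how many mRNA or protein molecules they
contain and at what molar concentration, how mobile their components are
(FRAP), how often two labeled species truly colocalize beyond chance, how
strongly a species partitions into the condensed phase, and how far the
signal's center of mass has shifted along the anteroposterior (AP) axis of
the cell. `rnpgranules` implements that whole tool chain for R.

## What it computes

| Quantity | Model / definition |
|---|---|
| Granule segmentation | Intermodes histogram threshold (iterative 3-point smoothing until bimodal, threshold = midpoint of the two modes), plus fixed and fraction-of-max thresholds; connected-component labeling (6/26 or 4/8 connectivity) |
| Morphometrics | volume, sphere-equivalent diameter, intensity-weighted centroid, aspect ratio = major/minor axis from FWHM of line profiles along the principal axes |
| Size distribution | Gaussian fit (mean, SD) of a diameter cohort |
| FRAP kinetics | FRAP(t) = I₀ + I₁·(1 − e^−(t−t_bleach)/τ); immobile fraction = (1 − I₀ − I₁)/(1 − I₀); t½ = τ·ln 2; double normalization with 0–1 rescale |
| Copy number | 1D Gaussian-mixture EM (BIC over K); unit intensity = mean of the largest-weight component; copies = intensity / unit |
| Molar concentration | copies / (N_A · volume) |
| Protein calibration | OLS line through a fluorophore dilution ladder; inverse prediction with extrapolation flags |
| Colocalization | object-based nearest neighbor within a 250 nm window; frequency = observed − mean of a mask-confined randomization null (default R = 100) |
| Partition coefficient | mean intensity inside condensates / mean intensity of the dilute phase (halo-excluded complement) |
| AP polarity | intensity-weighted center of mass − geometric mask center along the AP axis, also normalized by AP extent (posterior positive) |

Every quantity has a matching generator in the synthetic-microscopy module
(`generate_granule_image()`, `generate_two_channel_field()`,
`generate_frap_trace()`, `generate_intensity_population()`,
`generate_polarity_field()`, `generate_calibration_ladder()`) that produces
seeded data with exact ground truth.

## Worked example

```r
library(rnpgranules)

# a 50-granule field with the in vivo size distribution (400 +/- 129 nm)
params <- granule_field_params(field_shape = c(40, 200, 200),
                               voxel_size = c(100, 100, 100),
                               n_granules = 50, diameter_mean = 400,
                               diameter_sd = 129, min_separation = 2000,
                               seed = 7)
sim    <- generate_granule_image(params)
mask   <- threshold_image(sim$image, method = "fixed", value = 1e-9)
labels <- label_objects(mask)
labels
#> labeled_objects: 50 object(s), full connectivity
records <- measure_objects(labels, sim$image)
fit_size_distribution(records$equivalent_diameter_nm)
#> Gaussian size fit: 405.9 +/- 106.9 nm (n = 50)

# FRAP: recover kinetics from a noisy simulated trace (0.35 s frames, ~55 s)
ft  <- generate_frap_trace(frap_sim_params(I0 = 0.2, I1 = 0.5, tau = 10,
                                           n_postbleach = 157,
                                           noise_sd = 0.02, seed = 1))
fit <- fit_recovery(normalize_trace(ft$trace, rescale = FALSE))
fit
#> FRAP fit: I0 = 0.2101, I1 = 0.4983, tau = 10.464 s
#> immobile fraction = 0.3691, t1/2 = 7.253 s, residual RMS = 1.87e-02
```

The segmentation recovers all 50 simulated granules and their diameter
distribution; the FRAP fit returns the generating kinetics (τ = 10 s,
immobile fraction 0.375) within the noise of a single trace.

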