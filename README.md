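# facedysm

Quantification of facial dysmorphology from 2D anatomical landmarks, for
researchers and clinical geneticists studying rare disorders with small
patient samples.

Facial photographs annotated with a fixed 18-landmark configuration
(glabella, sellion, endocanthions, exocanthions, lower-eyelid points,
pronasale, subnasale, subalare points, lip and philtrum points, mouth
corners) are compared between a control group and a patient group with
**Euclidean Distance Matrix Analysis (EDMA)**:

1. each subject's coordinates are scaled by centroid size
   *CS = sqrt(Σᵢ ‖xᵢ − x̄‖²)*, removing overall scale;
2. each subject becomes a *form matrix* — the 18·17/2 = 153 Euclidean
   distances between all landmark pairs, a coordinate-system-free shape
   representation;
3. every distance is tested with the relative difference
   *D = (d̄_control − d̄_patient) / d̄_control* (*D* > 0 ⇒ shorter in
   patients) via a two-sample nonparametric bootstrap: subjects are
   resampled within groups (10,000 replicates by default), the replicate
   *D* values are sorted, 5% is trimmed from each tail (α = 0.10), and the
   distance is significant when 0 falls outside the retained range;
4. the **Facial Dysmorphology Score (FDS)** is the percentage of the 153
   distances that differ significantly;
5. a **staggered pseudo-subsample simulation** calibrates the FDS: pseudo
   patient groups containing *M* = 0…N true patients (topped up with
   controls) are contrasted against the remaining controls, 150 times per
   round; the p-value is the fraction of *M* = 0 (control-only) simulations
   whose FDS exceeds the observed one.

The package also reads/writes landmark CSV and TPS files, maps standard
68-point face-detector output onto the 18-landmark scheme (15 direct
indices plus 3 computed midpoints, via an editable YAML table), validates
automatic against manual landmarks by RMSE, and ships a synthetic cohort
generator with documented syndrome-like effect presets so the entire
pipeline is testable without restricted clinical data.

## Worked example

A synthetic cohort at a published study composition (79 controls, 11
Morquio-like patients), generated and analysed end to end:

```r
library(facedysm)

coh <- syndrome_cohort("MS", seed = 11)
fit <- edma_contrast(coh, patient_group = "MS", n_boot = 10000, seed = 12)
fit
#> EDMA contrast: control (n = 79) vs MS (n = 11)
#>   153 interlandmark distances, 10000 bootstrap resamples, alpha = 0.1
#>   statistic: relative difference
#>   significant distances: 104 of 153 (FDS = 68.0%)

top_differences(fit, k = 3)
#> Top 3 distances increased in patients (rel_diff < 0):
#>   crista_philtri_r -- crista_philtri_l: 31.9% increase in patients
#>   subnasale -- subalare_l: 27.7% increase in patients
#>   subalare_r -- subalare_l: 23.9% increase in patients
#> Top 3 distances decreased in patients (rel_diff > 0):
#>   pronasale -- subnasale: 28.8% reduction in patients
#>   pronasale -- labiale_superius: 18.2% reduction in patients
#>   pronasale -- crista_philtri_r: 13.4% reduction in patients

sim <- fds_simulation(coh, "MS", n_sims = 150, n_boot = 1000, seed = 13)
sim
#> FDS pseudo-subsample simulation: control (n = 79) vs MS (n = 11)
#>   rounds M = 0, 2, 4, 6, 8, 10, 11; 150 simulations/round; n_boot = 1000; alpha = 0.1
#>   observed FDS = 67.3%; p = 0 (strict rule)

summarize_rounds(sim)
#>    M n_sims     mean       min      max
#> 1  0    150 13.72113  3.921569 28.10458
#> 2  2    150 16.43573  5.228758 39.86928
#> 3  4    150 27.96078 14.379085 42.48366
#> 4  6    150 42.99782 26.143791 58.82353
#> 5  8    150 56.19608 42.483660 66.01307
#> 6 10    150 65.47712 59.477124 71.24183
#> 7 11    150 67.61656 65.359477 69.93464
```

Reading the output: the Morquio-like effect field widens the nose base and
philtrum and shortens nasal and midfacial heights, so about two-thirds of
all facial distances differ. No control-only simulation (M = 0 row: FDS
3.9–28.1%) reaches the observed 67.3%, hence p = 0 — the dysmorphology is
far beyond what sampling noise among controls produces — and mean FDS
climbs monotonically as rounds include more true patients.
`plot(fit)` draws the wireframe of top differences; `plot(sim)` the
per-round histograms.

A shell entry point over the same functions lives in
`inst/scripts/facedysm` (subcommands `generate`, `map68`, `rmse`, `edma`,
`fds`, `simtest`, `report`).

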