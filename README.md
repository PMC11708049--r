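# colidist

Quantification of the bacterial DNA-damage response around
colibactin-producing colonies.

Colibactin, the genotoxin of the *E. coli* *pks* island, damages the DNA of
neighbouring cells. With a *recA*-promoter YFP reporter in target cells
(constitutive CFP) and mCherry-tagged producers, the strength and spatial
reach of that damage can be measured on agar plates and in co-culture flow
samples. `colidist` implements the complete analysis chain for three such
assays, together with a synthetic-data generator so every stage can be
validated against known ground truth:

* **Spatial decay (dist₅₀).** YFP intensity along a cross-section from a
  producer colony is smoothed with a 20-sample moving window; the baseline
  is the mean of the 20 furthest samples; YFP₅₀ = baseline +
  (max − baseline)/2; **dist₅₀** is the distance of the first downward
  crossing of YFP₅₀ scanning outward from the peak. Contacting colony pairs
  use their own YFP₅₀; non-contacting pairs (edge gap ≥ 10 µm, gap samples
  masked) use the contacting YFP₅₀ averaged across replicates as a
  reference. For a noise-free exponential gradient of decay length λ,
  dist₅₀ = λ·ln 2.
* **Flow cytometry.** Hierarchical debris/singlet gating, CFP/mCherry
  reporter–producer classification, and percent-positive counting above the
  conservative cutoff mean + 3 SD of the t = 0 reporter distribution, fixed
  across the whole time course. Propidium-iodide lysis fractions use the
  same gating.
* **Replicate statistics.** Welch unequal-variance t-tests on
  biological-replicate means, CFU/mL back-calculation from 1:1 serial
  dilutions (factor 2^k), and exact Clopper–Pearson bounds on colony
  cross-contamination.
* **Synthetic scenes.** 16-bit CFP/YFP/mCherry rasters of lawns and colony
  pairs around a radial toxin field `A·exp(−(r−R)/λ)`, and labelled
  log-normal flow-event mixtures (responders, producers, debris, doublets,
  lysed cells) — bit-reproducible for a fixed seed.

## Worked example

```r
library(colidist)

# Three simulated producer colonies on reporter lawns, lambda = 100 um
lawn <- run_lawn_assay(n_colonies = 3, decay_length = 100, step = 1,
                       seed = 11)
lawn$results[, c("scene_id", "baseline", "max_signal", "dist50_um", "valid")]
#>     scene_id baseline max_signal dist50_um valid
#> 1 lawn_r1_c1    503.0       9387     70.03  TRUE
#> 2 lawn_r1_c2    506.0       9330     70.03  TRUE
#> 3 lawn_r1_c3    547.1       9392     69.07  TRUE
```

Each row is one colony: the tail baseline (~500 camera units), the smoothed
peak response, and dist₅₀. The ground-truth gradient has λ = 100 µm, so the
analytic half-max distance is 100·ln 2 ≈ 69.3 µm — the noisy estimates land
within a micrometre of it.

```r
pairs <- run_colony_assay(n_replicates = 3, pairs_per_replicate = 10,
                          gap = 50, seed = 12)
pairs$group_summary
#>            group mean_dist50_um   sd n_replicates
#> 1     contacting          86.22 0.62            3
#> 2 non-contacting          82.56 2.11            3
pairs$ttest
#> <welch_ttest> t = 2.8751, df = 2.343, two-tailed p = 0.08549
```

Both contact classes are simulated from the same toxin field, and the two
dist₅₀ estimators agree to a few micrometres; the Welch test on replicate
means does not reject equality — the contact-independence pattern on data
where it holds by construction. (dist₅₀ here is measured from the producer
colony edge and includes the smoothing-window offset, hence ~86 µm rather
than 69 µm; both groups share it.)

The methods vignette (`vignettes/quantifying-damage-gradients.Rmd`) walks
through the model, the estimators, all tunable parameters and the
generator's scope.

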