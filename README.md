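# callspace

Null-model tests of acoustic niche partitioning in assemblages of
co-calling species (built with frog choruses in mind), from raw call
audio to standardized effect sizes.

The acoustic niche hypothesis predicts that species calling together
partition acoustic space to limit signal interference. `callspace` tests
that prediction the way community ecology tests co-occurrence structure:
each observed assemblage (the species heard calling together in one
short recording) is compared against random assemblages of the same
richness drawn from its local species pool — every species recorded
within 50 km — and the comparison is summarised as a standardized effect
size,

    SES = (observed − mean(null)) / sd(null),

computed per assemblage for five acoustic-similarity measures:

* **PCA_All, PCA_Spectral, PCA_Temporal** — mean pairwise Euclidean
  distance in the first three principal components of a centred-and-scaled
  PCA over all six, the three spectral, or the three temporal call
  parameters;
* **spectral overlap** — mean proportion of overlap between species'
  90% log10 frequency bandwidths (sign-reversed in SES so that positive
  always means partitioned);
* **dominant-frequency distance** — mean |Δ log10 dominant frequency|.

The six call parameters (5%/95%/dominant frequency in log10 Hz; 90%
energy duration, relative peak time, note rate) are measured from mono
44.1 kHz WAV clips with a Welch-averaged 512-sample Hann spectrum, the
conventions of standard bioacoustic software. Mean SES per measure gets
a bias-corrected and accelerated (BCa) bootstrap CI (implemented from
scratch, cross-checked against `boot`), and a linear mixed-effects model
checks the observed-vs-null contrast against richness, pool size,
habitat and date covariates. A synthetic-data module generates call
audio and whole assemblage datasets with known partitioning structure
(`random`, `repulsion`, `attraction` assembly), so every stage is
testable without any field data.

## Worked example

Generate a 500-site synthetic dataset whose communities repel each other
in dominant frequency (β = 5), and run the full analysis:

```r
library(callspace)

d <- gen_dataset(synthetic_scenario(n_sites = 500, mode = "repulsion",
                                    beta = 5, seed = 42))
res  <- compute_ses(d$assemblages, d$calls, n_null = 1000, seed = 42)
summarize_ses(res$ses, n_boot = 10000, seed = 42)
```

```
           measure mean_ses ci_low ci_high   n prop_below_null_mean     verdict
1          pca_all    0.793  0.727  0.8584 500                0.850 partitioned
2     pca_spectral    1.040  0.982  1.0972 500                0.926 partitioned
3     pca_temporal   -0.134 -0.219 -0.0513 500                0.480  aggregated
4 spectral_overlap    0.847  0.792  0.8986 500                0.914 partitioned
5 domfreq_distance    1.041  0.983  1.0972 500                0.926 partitioned
```

Reading the table: the spectral measures recover the planted structure —
mean SES ≈ 0.8–1.0 with bootstrap CIs well above zero, and ~91% of
assemblages are less acoustically similar than their null expectation
for dominant-frequency distance. The assembly process never looked at
temporal traits, so PCA_Temporal stays near zero (its residual −0.13
reflects cluster-level sampling noise under strong repulsion; see the
methods vignette). On the matching `mode = "random"` dataset every
measure is `indistinct` with mean SES within ±0.06 of zero.

The same pipeline runs from CSV files on disk:

```r
cfg <- pipeline_config(calls = "calls.csv", assemblages = "occ.csv",
                       out_dir = "out", n_null = 1000, seed = 42,
                       lmm = "long")
run_pipeline(cfg)   # writes ses.csv, summary.csv, exclusions.csv, lmm.csv
```

and single calls are measured with `measure_call(read_wav("clip.wav"))`.

## Analysis workflow

The `analysis/` scripts rebuild the study end to end, writing tables
under `results/`:

1. `01_simulate.R` — the three synthetic datasets (random / repulsion /
   attraction assembly);
2. `02_measure_calls.R` — synthetic WAV clips, measured and compared to
   generator truth;
3. `03_observed_similarity.R` — observed per-assemblage similarity;
4. `04_null_model_ses.R` — 1,000-null SES analysis with BCa summaries;
5. `05_covariate_models.R` — observed-vs-null mixed models.

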