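---
title: "Null-model tests of acoustic niche partitioning: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-model tests of acoustic niche partitioning: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question and the statistic

The acoustic niche hypothesis holds that species calling together should
partition acoustic space — diverging in frequency or temporal structure —
to limit interference with their own signals. `callspace` tests this at
the assemblage level: an *assemblage* is the set of species detected
calling together in one short recording, and the test asks whether the
calls in real assemblages are less similar to each other than chance
predicts.

"Chance" is defined by a geographically constrained null model. For each
observed assemblage, random assemblages of the same richness are drawn
uniformly without replacement from the *species pool* — every species
recorded in any assemblage within 50 km of the focal site. Constraining
the pool geographically matters: comparing a desert assemblage against a
continent-wide pool would confound habitat filtering with acoustic
structure. Each random assemblage is scored with exactly the same
similarity code path as the observed one, and the result is a
standardized effect size per assemblage and measure:

$$\mathrm{SES} = \frac{\mathrm{obs} - \overline{\mathrm{null}}}{\mathrm{sd}(\mathrm{null})}$$

with the sample standard deviation (denominator $n-1$) over the null
values. For spectral overlap — a similarity, where the other four
measures are distances — the sign is reversed, so positive SES always
means *partitioned* (less similar than chance) and negative means
*aggregated*. Assemblages whose null distribution collapses
(`sd = 0`) are flagged degenerate and excluded from summaries rather
than producing infinities.

Across assemblages, the mean SES per measure is summarised with a
bias-corrected and accelerated (BCa) bootstrap confidence interval, plus
the proportion of assemblages less similar than their null mean
(equivalently `mean(ses > 0)`). A mixed-effects model then checks that
the observed-vs-null contrast survives covariates.

# Call parameters

Six parameters summarise a species' call, measured from a mono 44.1 kHz
single-call clip:

| parameter | units | definition |
|---|---|---|
| frequency 5% | log10 Hz | frequency splitting 5% of total spectral energy |
| frequency 95% | log10 Hz | frequency splitting 95% of total spectral energy |
| dominant frequency | log10 Hz | maximum-energy frequency bin |
| duration 90% | s | time holding the central 90% of envelope energy |
| peak time (relative) | 0–1 | position of the amplitude peak within the call |
| note rate | notes/s | discrete notes divided by call duration |

All frequencies are stored log10-transformed, because frequency
perception and production in vertebrates operate on a ratio scale; a
250 Hz gap means something different at 500 Hz than at 5 kHz.

The spectrum is a Welch average: Hann windows of 512 samples
(86.13 Hz bins at 44.1 kHz), 50% overlap, periodograms averaged over the
call. The percentile frequencies use the right-continuous convention —
the smallest bin at which cumulative energy reaches the target fraction —
on that averaged spectrum. The 90% duration is measured on the squared
smoothed envelope (5 ms moving average of the rectified waveform), as the
time between the 5% and 95% cumulative-energy instants. Notes are maximal
envelope runs above 10% of the envelope peak, with silent gaps shorter
than 10 ms merged into the surrounding note; both thresholds are exposed
as arguments, since "separated by silence" is a convention, not a law of
nature. Call bounds default to the first-to-last supra-threshold sample
but can be given explicitly for manually isolated calls. Dominant-frequency
ties break toward the lower frequency, and envelope-peak ties toward the
earlier instant, so measurement is fully deterministic; all six parameters
are invariant to rescaling the waveform amplitude.

Two conventions here are genuinely underdetermined by standard practice
and are therefore fixed and documented rather than inferred: the window
type/overlap of the averaged spectrum (Hann, 50%), and the use of
envelope rather than spectrogram energy for the 90% duration. Changing
them shifts parameter values slightly but coherently across species, and
the downstream analysis only consumes differences between species.

# Similarity measures

Five measures are computed per species pair and averaged over all
$\binom{n}{2}$ pairs of an assemblage:

* **PCA_All / PCA_Spectral / PCA_Temporal** — Euclidean distance in the
  first three principal components of a centred-and-scaled PCA over all
  six, the three spectral, or the three temporal parameters. The PCA is
  fitted once over *all* species in the analysis set, not per assemblage,
  so all pairs are scored in one common space. Component signs are fixed
  by forcing the largest-magnitude loading of each component positive.
  For the three-parameter subsets the three components span the full
  space, so those distances equal standardized-parameter distances.
* **Spectral overlap** — the two species' 90% bandwidths
  $[f_5, f_{95}]$ on the log10 scale intersect in a segment of length
  $L$; the reported proportion is the mean of the two directed
  proportions, $(L/b_a + L/b_b)/2$. This denominator choice is a declared
  convention: it is symmetric, bounded in $[0,1]$, and reduces to the
  obvious answer for equal bandwidths. Bandwidths are floored at one
  86.13 Hz bin (expressed in log10 units at 1 kHz) so a degenerate
  single-bin measurement can never divide by zero.
* **Dominant-frequency distance** — $|\log_{10} f_a - \log_{10} f_b|$.

Species-level parameters are one vector per species (species-typical
calls); if multiple clips are measured per species they should be
averaged on the stored scales before analysis.

# Filters and pools

Three dataset filters precede the null model: assemblages with fewer than
four species are removed (too few pairs to carry signal); assemblages
containing a species without the parameters a measure needs are removed
*for that measure group* — dominant frequency is available for more
species (literature values), so the dominant-frequency analysis retains
more assemblages than the six-parameter analyses; and assemblages whose
50 km pool contributes no extra species are removed, because their null
would reproduce the observed assemblage exactly. Pools are
boundary-inclusive (≤ 50 km, haversine on a sphere of radius
6371.0088 km) and are intersected with the parameter-complete species
set, so every null draw can be scored. Focal species stay in the pool —
the observed composition is a legitimate null draw — and sampling is
uniform over distinct pooled species by default, with occurrence-weighted
sampling available as an option.

Reproducibility uses one master seed with per-assemblage child streams
keyed by assemblage id, so SES values are bitwise reproducible and
invariant to processing order or subsetting.

# Inference

The BCa bootstrap of the mean SES is implemented directly: $B$ resampled
means; bias constant $z_0 = \Phi^{-1}(\#\{\bar x^* < \bar x\}/B)$ with
mid-rank handling of ties; acceleration $a$ from the jackknife skewness
of leave-one-out means; adjusted percentile levels
$\alpha_k = \Phi\!\left(z_0 + \frac{z_0 + z_k}{1 - a(z_0+z_k)}\right)$;
empirical quantiles (type 7) of the bootstrap means at those levels.
Setting $z_0 = a = 0$ recovers the plain percentile interval exactly,
which the test suite asserts, and endpoints agree with
`boot::boot.ci(type = "bca")` to Monte-Carlo precision. Known
limitation: like any BCa interval for a mean at $n \approx 50$, true
coverage sits slightly below nominal (simulations here put it near
94–95% at the 95% level).

The covariate model compares observed and null similarity per measure.
The default "long" form uses one row per assemblage for the observed
value and one for the per-assemblage null mean — using the null *mean*
rather than all 1,000 draws avoids pseudo-replication — with an
observed/null indicator interacting with richness and the number of
extra pooled species as fixed effects, and habitat, month, recording
date and assemblage as random intercepts. A "contrast" form
(observed − null mean per assemblage, sign-aligned so positive means
partitioned) is also offered; which quantities enter such a comparison
is an interpretation choice, so both are labelled as such. Grouping
factors in which every level has a single observation carry no estimable
variance and are dropped with a warning. Numerical fitting is delegated
to `lmerTest::lmer` (REML, Satterthwaite p-values); the package's
contribution is the model specification, covariate centring and
structured reporting. The five measures are modelled independently, with
no multiple-testing correction, matching how such analyses are
conventionally reported.

# The synthetic-data generator

The generator exists so the whole pipeline is testable end to end with
known ground truth, at two levels.

**Call audio.** A synthetic call is a train of Hann-enveloped tonal
notes with a designated loudest note; the generating parameters *are*
the measurement truth (dominant = carrier, note rate = notes/extent,
peak time = centre of the loudest note). Random specs span carriers of
800–6000 Hz, 4–10 notes, 2–12 notes/s and duty cycles of 0.25–0.55 —
representative of anuran advertisement calls.

**Assemblage datasets.** Defaults emulate a desk-scale continental
citizen-science dataset: 30 species; log10 dominant frequency
$\sim N(3.1, 0.3)$ (a 95% range of roughly 320 Hz–5 kHz, realistic for
a continental frog fauna); 90% bandwidth $\sim N(0.20, 0.05)$ truncated
at 0.02; temporal traits drawn *independently* of spectral traits; 500
sites in 5 clusters placed far enough apart (> 500 km) that every 50 km
pool is cluster-local, each cluster hosting a random 15-species local
pool; richness 4 + Poisson(2), capped at the pool; recording dates
uniform over one year; one habitat label per cluster. Community assembly
is uniform (`random`), or sequential with the next member joining with
probability $\propto \exp(\pm\beta \cdot d_{\min})$ where $d_{\min}$ is
the smallest dominant-frequency distance to the current members
(`repulsion`/`attraction`). At $\beta = 0$ every mode reduces exactly to
the null model's uniform sampler — the same function — which pins SES
calibration at zero by construction.

Repulsion acts on dominant frequency only, deliberately: a one-axis
mechanism gives interpretable recovery targets — the spectral measures
respond, the temporal measure is a built-in negative control whose
expected SES is zero.

What the generator does **not** emulate: real phylogenetic structure and
body-size–frequency allometry, uneven citizen-science sampling effort,
within-species call variation (temperature, region, plasticity), and
imperfect detection. Passing recovery tests therefore shows the
*pipeline* is correct and well calibrated, not that any particular real
fauna is partitioned.

# Problem sizes, precision, and known statistical limitations

The standard experiment scale used throughout the tests and the
acceptance script is 500 assemblages × 200 null draws (the analysis
scripts use the full 1,000). Two sampling-theory facts shape what can be
concluded at that scale:

* The per-assemblage SES has variance ≈ 1 under the random scenario, so
  a 500-assemblage grand mean carries a standard error of ≈ 0.045.
  Calibration checks at that size resolve the mean to roughly ±0.09 at
  95% confidence; a single dataset landing at, say, −0.057 on one
  measure is expected behaviour, not bias. Pooling datasets (or more
  assemblages) tightens this at the usual $1/\sqrt{n}$ rate.
* Under *strong* repulsion ($\beta = 5$) the sequential sampler
  concentrates each cluster's observed compositions onto few species
  subsets. The temporal control then inherits a cluster-level random
  offset — zero-mean over trait draws, but with only 5 clusters its
  standard deviation (~0.1) exceeds the assemblage-level bootstrap CI
  half-width (~0.09). The temporal negative control is therefore
  reliable in expectation and across replicate datasets, but a single
  dataset's CI can exclude zero either way. A hierarchical
  (cluster-level) bootstrap would widen the interval appropriately; it
  is not implemented because the field convention, which this package
  follows, treats assemblages as the resampling unit.

Numerical conventions worth knowing: degenerate null distributions are
flagged, not dropped silently; the overlap bandwidth floor prevents
division by zero for single-bin calls; BCa intervals that fail to
contain the sample mean (pathological skew) warn rather than silently
report; and every randomized stage (null draws, bootstrap, generator)
derives child seeds from one master seed by hashing stable identifiers,
so results do not depend on iteration order.
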