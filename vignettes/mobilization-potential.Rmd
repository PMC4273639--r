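---
title: "Measuring community mobilization potential: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring community mobilization potential}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mobipot)
```

## The assay and its calculus

A solid-surface filter mating deposits a fluorescently tagged donor strain
and a recipient community at high density (30,000 cells/mm², 1:1
donor:recipient) on a 270 mm² membrane. After incubation, transconjugant
microcolonies de-repress a *gfp* marker and are counted by fluorescence
stereomicroscopy over a scanning zone of 7 × 7 fields of 980 × 732 µm —
about 13% of the filter. The transfer frequency is the scanned count scaled
to the whole filter, divided by the recipients *initially placed* on the
filter (not those that later formed microcolonies): "transconjugants per
recipient", T/R.

Five matings feed the mobilization calculus: the conjugal plasmid into the
community (`f_conj_comm`) and into an isogenic recipient (`f_conj_intra`);
the mobilizable plasmid into the community (`f_retro_comm`,
retromobilization by the community's own conjugal plasmids) and into an
isogenic recipient already carrying the mobilizing plasmid
(`f_retro_intra`); and the mobilizable plasmid from a donor co-hosting the
mobilizer (`f_direct_comm`). The derived quantities are plain ratios:

* permissiveness equivalents `f_conj_comm / f_conj_intra` — normalising by
  the intrastrain mating removes donor promiscuity and contact-saturation
  effects that are common to both;
* retromobilization probability `f_retro_intra / f_conj_intra` — the two
  matings share their first step (conjugal transfer from the recipient side
  into the donor), so the ratio estimates the conditional probability of
  the subsequent mobilization step;
* maximal mobilization potential `f_retro_comm / p_retro` — the community
  mobilization frequency if every acquired conjugal plasmid performed the
  mobilization step; and its normalisation by `f_conj_comm`.

`p_retro` is an empirical ratio of measured frequencies; values above 1 are
reported with a warning rather than clamped, because a ratio above 1
indicates an assay anomaly that clamping would hide. Intermediate values
are carried at full precision and rounded only for display (equivalents to
3 decimals, probabilities to 0.1%, frequencies to 3 significant figures);
this matters, e.g. the maximal potential is reproduced from the unrounded
probability 0.47386, not from 0.474.

A useful algebraic identity, used as an invariant test: composing the two
mobilization steps gives exactly
`(f_retro_comm * f_conj_intra) / (f_retro_intra * f_conj_comm)` for the
potential in equivalents. All report quantities except `M_max` are
invariant under multiplying every frequency by a common constant; `M_max`
scales linearly.

## Why ratios: counting biases cancel

Quantification is limited to the brightly illuminated elliptic central area
of each field and to objects strictly larger than 4 µm², while the
scale-up to the filter divides by the full scanned area. Absolute
frequencies therefore carry a multiplicative attenuation (ellipse area
fraction π·0.9²/4 ≈ 0.64, times the fraction of microcolonies above the
area cutoff). The attenuation is identical across matings quantified under
one convention, so it cancels in every ratio quantity — this is the
principal reason the framework is built on equivalents rather than absolute
frequencies. The workflow script `analysis/03_frequencies.R` demonstrates
the effect on synthetic data, where the truth is known.

## The synthetic image model

With no deposited image data, the package generates its own two-channel
fields with exact ground truth (`imaging_truth()`, `generate_field()`,
`generate_filter_experiment()`). The model emulates the features the
detection pipeline must survive: dense red donor microcolonies, rare green
transconjugant microcolonies placed within 20 µm of a donor, an elliptic
illumination profile that is flat over the central 90% of the inscribed
ellipse and falls to zero outside it (poorly illuminated corners), a
uniform background at 10% of a typical colony peak, additive Gaussian
noise, and per-field transconjugant counts drawn from a Poisson law with
mean `true_frequency × recipients_per_field`.

Parameter choices, made once as plausible values for a stereomicroscope at
40× with a cooled camera (the assay literature reports no intensity
statistics or pixel calibration, so these are free knobs):

* `pixel_scale_um = 1` (configurable);
* colony peak intensity 1 ± 10%, `noise_sd = 0.05` (SNR ≈ 20 — GFP
  microcolonies are bright objects), `background_level = 0.1`;
* 200 donors per field with radii 4–10 µm, visibly tiling the field;
* transconjugant areas uniform on 1–20 µm², deliberately straddling the
  4 µm² cutoff so the area filter is exercised at its boundary;
* the illumination flat core matches the default analysis ellipse (0.9), as
  an analyst chooses the ellipse to cover the evenly lit area.

Blobs default to an antialiased hard disk with a half-pixel edge rather
than a Gaussian. The reason is the area contract: the thresholded area of a
Gaussian profile grows like `2πs² log(peak/threshold)` and thus depends
strongly on where the automatic threshold lands, which makes "nominal blob
area" ill-defined and lets 2 µm² blobs exceed the 4 µm² cutoff under any
low threshold. The disk keeps pixel area ≈ πr² for any mid-range threshold.
A Gaussian profile (`blob_profile = "gaussian"`, FWHM = colony diameter)
remains available. Not modelled, deliberately: PSF convolution, chromatic
aberration, channel crosstalk, colony growth or merging dynamics. Passing
the synthetic suite therefore shows the pipeline's arithmetic and
segmentation logic are sound under realistic noise and illumination — not
that it is robust to every optical artefact of real stereomicroscopy.

## The detection pipeline

Per channel: background subtraction → equalization → elliptic ROI →
automatic segmentation (`count_field()`).

* **Background**: grayscale morphological opening with a disc of radius
  25 µm, much larger than a microcolony; the opening never exceeds the
  image, so the subtraction is non-negative and preserves small bright
  objects by construction. A radius below ~2 px is rejected as degenerate.
* **Equalization**: a linear min–max contrast stretch to [0, 1]. It
  preserves rank order exactly and is idempotent. Percentile-clipped
  variants are available but not default: when bright signal occupies less
  than the clip percentile of pixels — a transconjugant channel holds a
  handful of blobs in 7 × 10⁵ pixels — clipping maps the signal into the
  top of the noise range and destroys the separation the threshold needs.
* **ROI**: an axis-aligned centred ellipse with semi-axes 0.9 × half-width
  and half-height (configurable); membership of an object is decided by its
  centroid, a single unambiguous rule for boundary objects.
* **Segmentation**: threshold chosen automatically from the ROI pixels by
  the triangle method, with a noise floor of median + 6 MAD; 8-connected
  labelling; objects strictly larger than 4 µm² (pixel count × pixel
  scale²) reported, sorted by centroid. Otsu's method is available
  (`threshold_method = "otsu"`) and behaves well on the dense donor
  channel, but on a sparse channel its between-class criterion is maximised
  by splitting the background noise in half, flooding the frame with
  foreground; the triangle geometry targets exactly the
  one-peak-plus-bright-tail histogram this assay produces. The noise floor
  handles fields with no true signal at all, where any histogram method
  must otherwise pick a threshold inside the noise: at 6 robust SDs, the
  expected number of false noise pixels in a field is ≪ 1, and stray
  specks are removed by the area cutoff. Touching colonies are not split —
  the assay counts microcolonies and the manual-correction ledger
  (`apply_corrections()`) covers rare merges, mirroring the manual control
  step of the original protocol.

Counting is invariant to global linear intensity rescaling (the stretch
normalises it away) and to the illumination profile for colonies inside the
ROI (background subtraction removes the smooth component).

## Frequency estimation and its uncertainty

`transfer_frequency()` composes the scanned-to-filter scale-up (scanned
fraction 49 × 980 × 732 µm² / 270 mm² ≈ 13.0%) with the
initially-placed-recipient denominator (4.05 × 10⁶). Replicate filters are
aggregated as mean ± SEM (sample sd/√n; undefined and flagged for n = 1).

One caution the synthetic recovery study makes explicit: with triplicate
filters, the pivot (mean − truth)/SEM follows a t distribution with 2
degrees of freedom, for which a ±3 SEM band covers only ≈ 90.5% — not the
≈ 99.7% a normal intuition suggests. The acceptance study
(`frequency_recovery_study()`) measures exactly this coverage on the exact
Poisson generative model; values near 90% are the statistically correct
outcome for n = 3, not an estimator defect (the estimator itself is
unbiased, as the recovered mean shows).

Ratio uncertainty is propagated either by the first-order delta method
(`sd(a/b) = (a/b)·√((sa/a)² + (sb/b)²)`) or by a seeded nonparametric
bootstrap over per-replicate frequencies with percentile intervals. The two
agree on interval width for tight replicate sets once enough replicates
exist for the resampled mean to be reasonably continuous; with only three
replicates the bootstrap distribution is too discrete for a meaningful
percentile interval, so the delta method is the default.

## The mating simulator

`simulate_conjugation()`, `simulate_direct_mobilization()` and
`simulate_retromobilization()` implement a well-mixed, single-contact
Bernoulli model: each recipient independently experiences at most one
observable event, matching microcolony-based quantification where one
transconjugant microcolony is one event. Event counts are exact binomial
draws (retromobilization is a binomial thinning of the step-1 successes, so
retro events can never exceed them). Deliberately out of scope: spatial
structure, microcolony growth, secondary retransfer, conjugal co-transfer
during direct mobilization (it does not change first-transfer counts), and
plasmid loss. The simulator's role is estimator validation: feeding
realized frequencies through `build_report()` must recover the simulated
parameters — `p_retro` converges to the true `p_mob_given_conj` and the
permissiveness equivalents to the true permissive fraction as the recipient
number grows. `p_retro_recovery_study()` runs this at the intrastrain
scale of the assay (`p_conj = 1.76 × 10⁻³`, `p_mob_given_conj = 0.474`,
10⁶ recipients, 100 seeds).

## Problem sizes and determinism

The shipped studies use: 49 rendered fields (980 × 732 px) for the
detection score; 100 repetitions × 3 count-level replicates for frequency
recovery; 100 seeds × 10⁶ recipients for simulator recovery; 10³ random
frequency sets for the algebraic identity; the workflow demo uses 3 × 16
rendered fields. Every stochastic component takes an explicit integer seed
and is bit-reproducible under it, including TIFF bytes; derived seeds are
drawn below 2³¹.

## Known limitations

* The original quantification macro is proprietary; background
  subtraction, "best-fit equalization" and "automatic segmentation" are
  reimplemented here as the standard parameter-free choices stated above,
  not as a byte-level reproduction.
* Absolute synthetic frequencies inherit the counting-convention
  attenuation discussed above; only ratios are bias-free.
* The calculus assumes the intrastrain mating is a valid ceiling for the
  community mating (same donor physiology and contact regime); violations
  show up as equivalents above 1, which are reported, not suppressed.
* For plasmids that are long-term maintained and retransferred, absolute
  frequencies rather than equivalents remain the quantity of interest.
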