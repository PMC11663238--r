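---
title: "Scoring anatomical errors in AI-generated human images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring anatomical errors in AI-generated human images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anatscore)
```

## The problem

Text-to-image models produce photorealistic people with characteristic
anatomical failures — six-fingered hands, fused limbs, impossible joint
orientations. Judging whether one model is anatomically more plausible than
another requires a structured human-annotation rubric rather than ad-hoc
impressions, and the rubric in turn needs tooling: validated data capture,
a defensible aggregate score, agreement statistics for the annotators, and a
randomisation scheme for assigning images to them. `anatscore` implements
that tooling for a fixed 5 × 5 × 3 taxonomy: five anatomical regions (face,
torso, hands, limbs, feet), five error types (proportion, extra,
orientation, configuration, missing) and three ordinal severities (*a* low,
*b* medium, *c* severe).

## The scoring model

One annotation records, per image and annotator, the expected part count
$m_i$ of each region (parts present, or expected present given the number of
people and the framing) and the error counts $n_{(ij)k}$ per
(region $i$, error type $j$, severity $k$). The **proportion of errors** of a
cell is

$$PE_{(ij)k} = \frac{n_{(ij)k}}{m_i},$$

and the **cumulative score** of the annotation contracts the proportions
with severity weights $w_a \le w_b \le w_c$:

$$C = \sum_{i=1}^{5}\sum_{j=1}^{5}
      \left(w_a\,PE_{(ij)a} + w_b\,PE_{(ij)b} + w_c\,PE_{(ij)c}\right).$$

The defaults $w = (0.2, 0.5, 1.0)$ down-weight mild errors; with them
$C \in [0, 25]$. Two conventions make every proportion well defined:

* **one denominator per region.** The expected part count is stored once per
  region and shared by all five error types, matching the verbal definition
  of $m$ as the number of parts present. Nothing in the error taxonomy makes
  a region's part count depend on which error is being counted.
* **counts are bounded by the denominator.** Validation enforces
  $\sum_k n_{(ij)k} \le m_i$ per (region, type) — a spurious extra limb is
  charged against the region's site count — so $PE \in [0,1]$ always. A
  region cropped out of frame has $m_i = 0$, admits no error rows, and its
  cells contribute 0.

Double annotations are scored independently per (image, annotator); the
package never reconciles or averages them, so with the reference design all
300 annotations enter group statistics as observations.

### Overall severity levels

Cumulative scores are mapped to *low / medium / high* labels per annotator:
scores at or below the annotator's own 0.5 quantile are low, at or below the
0.75 quantile medium, above it high. Quantiles use linear interpolation
between order statistics (R's default type 7) and the boundaries use `<=` on
both thresholds; both choices are arbitrary at the margins and are fixed
here for reproducibility. Thresholds always come from the annotator's full
score distribution, never a per-model or per-prompt stratum, which makes the
labels a *within-annotator* normalisation: they absorb differences in
annotator strictness, at the cost that the same score can receive different
labels from different annotators.

## Inter-rater agreement

Agreement on the double-annotated subset is measured with Krippendorff's
alpha, $\alpha = 1 - D_o/D_e$, computed from the coincidence matrix: all
values assigned to the same unit are paired, each pair weighted
$1/(m_u - 1)$; $D_o$ averages a difference function over those
coincidences and $D_e$ over all pairings of the pooled values. The
implementation supports the nominal ($\delta = \mathbb{1}[v \ne v']$),
ordinal (squared cumulative rank-frequency distance) and interval
($\delta = (v - v')^2$) metrics and missing entries; it is written from
first principles and checked in the test suite against an independent
brute-force enumeration on small matrices.

Three representations of the annotations are assessed:

1. **cumulative score** per image — interval level. (A ratio metric would
   also be defensible since scores are non-negative with a true zero;
   interval is the common default for such scores and is what we fix.)
2. **overall severity** per image — ordinal level on low < medium < high.
3. **binary category** — one nominal unit per (image, region × type cell),
   25 per image, valued 1 if the annotator recorded any error in the cell at
   any severity. The 25-entry vectors are pooled into a single alpha per
   annotator pair rather than averaged per cell, which yields one
   coefficient per pair.

Pairwise alphas are restricted to the units both members of a pair
annotated (no chaining through third raters); the reported average is the
arithmetic mean over pairs with at least one shared unit. Alpha is undefined
when the pooled values carry no variation or no unit was rated twice; such
pairs are reported as `NA`, never silently dropped into the average as
zeros.

One property worth knowing: if two annotators submit *identical*
annotations for every shared image, their cumulative-score and
binary-category alphas are exactly 1, but their overall-severity alpha need
not be — the severity labels are thresholded on each annotator's personal
score distribution, so identical scores can straddle two different personal
thresholds. This is a feature of within-annotator normalisation, not a bug,
and the test suite pins it down.

## Group comparisons

`summarize_annotations()` partitions scored annotations by model or prompt
and reports the group's annotation count, mean and sample variance (n − 1)
of the cumulative score, and per-severity **aggregate scores**: unweighted
sums of $PE$ over all annotations and cells of the group. Weights enter
only the cumulative score; keeping the aggregates unweighted preserves the
identity

$$\frac{w_a A + w_b B + w_c C_{\mathrm{agg}}}{n} = \bar{C},$$

which links a published severity-aggregate table to the published group
means and is verified in the acceptance tests. For the per-cell dimensions
(error type, region) only aggregates are reported — the cumulative score is
a per-image quantity and has no meaningful per-cell mean.

`welch_t()` implements the unequal-variance t test from summary statistics
(Welch–Satterthwaite degrees of freedom, two-sided p), so published group
summaries are directly testable. Raw p values are returned without
multiplicity correction; callers running many contrasts should adjust them
(`stats::p.adjust`). Recomputing published model contrasts from *rounded*
summary tables reproduces the published statistics only approximately
(−6.89 / −4.66 vs −6.72 / −4.67 from unrounded data) — the package's tests
document this rather than chase it.

## Annotation allocation

`allocate_annotations()` assigns images to annotators under the constraints
of a double-annotation design: an exactly sized doubled subset (fraction
rounded half to even), stratified over (model, prompt) cells by
largest-remainder apportionment; per-stratum slot shares within 1 of
proportionality (each annotator receives the floor or ceiling of
$k_s/A$ slots of stratum $s$); global loads within 1 (remainder slots go to
the currently least-loaded annotators, which preserves a max–min spread of
at most 1 by induction); and two *distinct* annotators per doubled image
(the pair with the largest remaining stratum capacities, which is feasible
because stratum capacities differ by at most 1). The plan is a
deterministic function of the seed, and the global RNG state is left
untouched. Exact ±1 proportionality of the *marginal* model and prompt
shares simultaneously is a three-dimensional controlled-rounding problem
with no general solution, so the package guarantees ±1 at the stratum level
— which implies marginal deviations bounded by the number of strata in the
margin — and exact balance of the totals.

## The synthetic generator

`generate_annotations()` simulates the entire pipeline so every statistical
operation is testable without any real annotation data. Per image, region
denominators are `round(person_count × per-person parts × visibility)`
(per-person parts: 1 face, 1 torso, 2 hands, 4 limbs, 2 feet); per (region,
type) cell the total error count is drawn
$\mathrm{Binomial}(m_i,\ \min(1, \text{rate} \times \text{difficulty}))$
and then split across severities by the model's severity mix (multinomial
thinning). Drawing the total first and splitting it means severity counts
can never exceed the denominator, so no truncation rule is needed and every
generated set validates cleanly by construction; under this model
$E[PE] = \text{rate} \times \text{difficulty}$ exactly, which gives the
closed-form expectation $E[C] = \sum_{ij} p_{ij} (w \cdot \text{mix})$
used by `recover_parameters()` (reducing to $25r$ for a uniform rate, pure
severity-c mix, unit difficulty and full visibility).

The second annotation of a doubled image is the first with each cell's
error *presence* flipped independently with probability
`annotator_noise` — a flipped-on cell receives a single error with severity
drawn from the mix. Presence-flipping is the simplest mechanism that spans
the agreement range: noise 0 duplicates annotations exactly (binary and
cumulative alphas 1) and noise 0.5 with symmetric cell prevalences makes
the two annotations independent (alpha near 0).

### Default conditions

The defaults reproduce the reference study design — 3 models × 10 prompts ×
8 images = 240 images, 4 annotators, 25% double annotation (300
annotations, 75 per annotator, 60 doubled) — and were calibrated once to
its reported outcome level:

* per-model uniform cell rates 0.0758 / 0.1201 / 0.1416 with severity mixes
  (0.537, 0.275, 0.188), (0.337, 0.298, 0.365), (0.334, 0.280, 0.386),
  chosen so the expected per-image severity profiles match the reported
  per-model aggregate scores (the strongest model's unreported "a"
  aggregate was back-solved from its reported mean);
* prompt difficulty multipliers averaging 1, with the hardest group scene at
  2.52 (its reported mean relative to the grand mean) and plausible ordering
  (groups > unusual single-person poses > couples), person counts from the
  prompt texts, and feet visibility 0.5 for waist-up scenes;
* `annotator_noise = 0.25`, which reproduces the reported *poor* agreement
  level (binary-category average alpha ≈ 0.45).

What the generator does **not** emulate: overdispersion between images of
one prompt (real generations vary more than a binomial), correlated errors
across regions of one figure, annotator-specific strictness or drift, and
severity confusion (real disagreement is often about grade, not presence).
Passing tests therefore demonstrate the correctness of the statistical
machinery under the design's sampling structure, not the behaviour of any
real generator or annotator. Simulated between-group t statistics, for
instance, run larger than observed ones because binomial variance
understates real image-to-image spread.

## Problem sizes and numerical choices

The test suite works at the design's native sizes: full 240-image /
300-annotation sets for shape and agreement checks, 200–400 images for
law-of-large-numbers and recovery checks, 1000 random annotations for the
monotonicity/linearity properties, 1000 random configurations for the
allocation invariants, and 1000 simulation replicates for the type-I-error
check of the model comparison. Other fixed choices: sample variance with
n − 1; quantile type 7; `round()`'s round-half-to-even for doubled-subset
sizing; ties in allocation broken uniformly at random under the seed;
undefined alphas raised as a typed condition (`anatscore_alpha_undefined`)
and surfaced as `NA` in pairwise tables.

## A worked example

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 1)  # all randomness flows through this seed
set <- generate_annotations(cfg)
validate_annotations(set)          # 0 rows
summarize_annotations(set, "model")
pairwise_agreement(set, "binary_category")$average
compare_groups(set, "prompt", "beach", "baby")
```

## Limitations

The package scores *annotations*, not images: it contains no computer
vision and inherits every subjectivity of the human rubric. The agreement
module implements Krippendorff's alpha only (no kappa family, no bootstrap
confidence intervals). The allocation module balances load and strata but
does not model annotator preferences or time budgets. The on-disk formats
are this package's own; converting another project's annotation exports
requires a small mapping script.
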