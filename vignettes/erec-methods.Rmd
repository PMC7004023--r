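---
title: "Measuring effective refractive error coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring effective refractive error coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erec)
```

## The indicator

Uncorrected refractive error is one of the two leading causes of vision
impairment worldwide, and it is almost always correctable with spectacles or
contact lenses. *Effective refractive error coverage* (eREC) measures both
dimensions that universal health coverage cares about — access to correction
and the quality of that correction — from a population-based survey. Writing
$a$ for people with met need, $b$ for under-met need and $c$ for unmet need:

$$\mathrm{eREC} = \frac{a}{a + b + c} \times 100\%, \qquad
  \mathrm{REC} = \frac{a + b}{a + b + c} \times 100\%,$$

and the relative quality gap, the share of coverage that is under-met, is
$1 - \mathrm{eREC}/\mathrm{REC}$. REC (refractive error coverage) counts
anyone whose impairing refractive error has been corrected at all, so the
difference between the two is purely the quality element.

## Classifying a survey participant

Need and outcome are judged on better-eye visual acuity against a
threshold, by default 6/12 — the WHO cut-off for mild distance vision
impairment — for both roles. Four acuity measurements can enter the
decision:

* **UCVA**, uncorrected acuity, measured on everyone;
* **CVA**, acuity with the person's own spectacles or contact lenses,
  measured on wearers;
* **PinVA**, pinhole acuity (over correction for wearers), which
  neutralises most refractive error and so separates refractive from
  non-refractive impairment;
* **BCVA**, acuity after fresh refraction, when a survey refracts.

The flowchart is: a person whose better-eye UCVA meets the need threshold
has **no need** (even if they own correction). Otherwise, a non-wearer is
**unmet** if pinhole/refraction clears the need threshold and has **other
vision impairment** (e.g. cataract) if it does not. A wearer whose CVA meets
the outcome threshold has **met need**; failing that, they are **under-met**
if pinhole-over-correction or new refraction clears the need threshold, and
other vision impairment otherwise. When the measurement that would decide is
missing the person is **indeterminate**. Indeterminate and
other-vision-impairment participants are excluded from the eREC numerator
and denominator but are always reported alongside it, because silently
dropping them would hide both data-quality problems and non-refractive need.

Three design choices in this implementation deserve a note:

* **BCVA precedence.** When a survey records both pinhole and
  best-corrected acuity, BCVA decides the improvement test: refraction is
  the more definitive measure of refractive correctability.
* **Unequal thresholds.** The outcome threshold applies only to the met/not
  met decision for wearers; the under-met versus other-VI split always uses
  the need threshold, because it asks whether refractive error is the cause
  of the residual impairment. With a stricter outcome threshold (say 6/6 on
  top of a 6/12 need threshold) a wearer whose CVA is between the two still
  requires a passing improvement test to count as under-met; the flowchart
  is applied literally rather than inferring correctability from CVA.
* **Contradictions.** A wearer whose corrected acuity is worse than their
  uncorrected acuity is classified exactly as the thresholds dictate — the
  categories are defined purely by threshold predicates — but such records
  increment a data-quality counter attached to the classified table.

## Acuity arithmetic

All comparisons happen on the logMAR scale, $\log_{10}$ of the minimum
angle of resolution, where a Snellen fraction $n/d$ maps to
$\log_{10}(d/n)$: 6/6 is 0.0, 6/12 is 0.301, 6/60 is 1.0, and larger is
worse. 20-foot notation is converted by ratio equivalence (20/40 is the
same line as 6/12). Because survey acuities are categorical chart lines
rather than continuous measurements, comparisons use an absolute tolerance
of 1e-6 logMAR: recorded lines compare exactly, and "6/12 or better" versus
"worse than 6/12" is an exact dichotomy. If a survey records continuous
logMAR (letter-by-letter scoring), values a hair above 0.30 will fall on
the "worse" side; that convention is the user's to set via the threshold,
and interpolated scoring is out of scope here. The low-vision categories
CF, HM, PL and NPL are mapped to ordinal sentinels 2.0, 2.3, 2.6 and 3.0
logMAR. Any fixed strictly increasing assignment would do: every sentinel
is worse than any plausible need threshold, and classification depends only
on order, never on the magnitude of these codes.

Missing acuities stay missing through the better-eye reduction (one seeing
eye suffices; two missing eyes propagate as missing) so that missingness
surfaces as an indeterminate classification instead of quietly inflating
unmet need.

## Estimation

`tabulate_need()` counts categories and sums sampling weights;
`erec()`/`rec()` form the coverage ratios either from unweighted counts or
as a ratio of weight sums (a standard ratio estimator for a domain
proportion — scaling all weights by a constant changes nothing). A zero
denominator (nobody in need) yields a flagged undefined estimate carrying
its counts, never a silent `NaN`.

Two confidence-interval methods are provided, chosen to match common survey
practice. The closed-form Wilson score interval applies to unweighted
proportions and behaves correctly at the boundaries (lower bound 0 at zero
successes). When weights or cluster sampling matter, a seeded percentile
bootstrap resamples primary sampling units (or persons, when no cluster
variable exists) with 1,000 replicates by default and recomputes the
weighted estimator per replicate. Default confidence level is 95%.

Estimates can be disaggregated over any stratum columns (sex, residence,
socioeconomic position, disability, ...), each stratum getting its own
interval, and directly standardised against an external population table:
the standardised value is $\sum_s w_s \, \mathrm{eREC}_s$ with $w_s$ the
reference population shares, which must cover every stratum and sum to 1
(tolerance 1e-9). A stratum with nobody in need cannot be standardised and
raises an error suggesting coarser strata. Every report also includes the
6/12–6/12 threshold pair even when other thresholds are requested, so that
results remain internationally comparable, and all arithmetic is done on
unrounded proportions — rounding (half away from zero, so 37.5 displays as
38) happens only at serialisation.

## The synthetic cohort generator

There are no public individual-level survey datasets with the full
UCVA/CVA/PinVA battery, so the package generates its own validation
cohorts. Per person, independently:

| parameter | meaning | default |
|---|---|---|
| `re_prevalence` | vision-impairing refractive error | 0.3 (or an age-sex table) |
| `uptake` | possession of correction, given need | 0.5 |
| `quality` | correction achieves the outcome threshold | 0.8 |
| `other_vi_prevalence` | non-refractive impairment | 0.05 |
| `missing_pinhole_rate` | pinhole not measured | 0 |
| `acuity_jitter` | one-line chart noise | 0 |

Acuities are then emitted on standard chart lines consistent with the
latent state: refractive error puts better-eye UCVA on a line worse than
6/12 with pinhole clearing; a good correction puts CVA at 6/12 or better; a
poor one leaves CVA worse while pinhole-over-correction clears;
non-refractive impairment blocks the pinhole regardless of refractive
status, which is why such people drop out of the denominator without
biasing coverage. The fellow eye is drawn at or worse than the better eye.
Under this independence structure the generative coverage has closed forms
— eREC $= \mathrm{uptake} \times \mathrm{quality}$, REC $=$ uptake, quality
gap $= 1 - \mathrm{quality}$ — which is exactly what makes
parameter-recovery experiments possible: `recovery_experiment()` repeats
generate–classify–estimate across seeds and reports bias and empirical
interval coverage. The defaults describe a middle-income setting with
substantial burden and partially effective services; they were fixed once
as the package's reference conditions.

What the generator deliberately does **not** emulate: correlated eyes
beyond the better/worse ordering, continuous acuity noise and test–retest
error, spatial or cluster structure in prevalence, non-compliance (owners
not wearing their correction — undetectable in a survey by design), and
realistic sphere/cylinder refraction. Passing recovery tests therefore
demonstrates that the pipeline is internally consistent and statistically
calibrated under the stated model, not that any particular field survey is
free of measurement problems.

`acuity_jitter` shifts drawn lines by one chart step with the given
probability but clamps at the need/outcome boundary so the latent category
is preserved; it exercises robustness of the parsing and comparison layers,
not misclassification (which would change the estimand).

## Numerical and reproducibility choices

Problem sizes in the test suite were chosen to make the statistical checks
sharp while keeping the suite quick: oracle equivalence runs on 10,000
randomised records, parameter recovery on 50 replicates of n = 10,000
(binomial standard error ≈ 0.009 on the eREC scale, so a 0.01 bias bound is
meaningful). All randomness — cohort generation and bootstrap resampling —
is driven by explicit integer seeds through R's default RNG, and both the
generator and the command-line `simulate`/`compute` paths are byte-for-byte
reproducible given a seed. RNG state is restored after seeded operations so
library calls do not perturb a caller's stream.

## Known limitations

Near-vision/presbyopic need is a separate indicator with different
measurements and is intentionally out of scope, as are imputation of
missing acuities, small-area estimation and eye-level (rather than
person-level) coverage. The Wilson interval ignores weights and design
effects; for weighted or clustered designs use the bootstrap. Direct
standardisation requires every stratum to contain people in need — sparse
strata should be coarsened before standardising.
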