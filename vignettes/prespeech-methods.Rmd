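---
title: "Gaze-speech alignment and connected-speech metrics: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gaze-speech alignment and connected-speech metrics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prespeech)
```

## The analysis problem

In a picture description task, a speaker views a scene (here one of two
pictures, the culturally adapted *Han River* scene or the standardized
*Beach* scene) and describes it in connected speech while an eye tracker
records fixations at 1,000 Hz on a 1680 x 1050 px display. Three families
of dependent measures are computed per trial (one participant x picture
session):

* **Informativeness** — Correct Information Units (CIUs) per minute. A CIU
  is a word that is intelligible in context *and* accurate, relevant and
  informative about the stimulus; CIUs are a subset of the counted
  intelligible words.
* **Productivity** — noun and verb tokens and types per utterance. Nouns
  include common nouns, proper nouns and pronouns (pronouns take case
  marking and refer like content nouns in Korean); verbs include main and
  auxiliary verbs (auxiliaries are semantically independent verbs in
  Korean serial verb constructions).
* **Pre-speech fixations** — for each utterance that describes a specific
  area of interest (AOI), the fixations on that AOI in the planning window
  that runs from the onset of the *previous* utterance to the onset of the
  current one, counted and summed in duration, then divided by the number
  of AOI-related utterances.

The inferential layer compares two age groups (24 younger, 22 older
participants) across the two pictures with mixed-design ANOVAs and partial
eta squared effect sizes.

The package deliberately separates *judgment* from *computation*. Part of
speech, intelligibility, CIU status, boundary markers, contextual
connection, and utterance-to-AOI mapping are human (coder) judgments in
the original workflow; they enter the pipeline as token/utterance
annotations and are never inferred from text or audio. The pipeline's job
is everything downstream of those annotations: rule-based utterance
segmentation (as a verification of coder boundaries), counting,
normalisation, geometry, temporal alignment, and inference.

## Utterance segmentation rules

An utterance is a sentence or a shorter unit. The rule engine
(`segment_utterances()`) applies the Korean-convention segmentation rules
to an annotated token stream:

1. Break after a token carrying a **sentence-ending particle** (e.g.
   *-ta*), unless the coder flagged it as contextually connected to the
   next word.
2. A **conjunction** (e.g. "and") opens a new utterance, which runs to the
   next sentence-ending particle. The engine also closes the preceding
   utterance at that point; whether a mid-utterance conjunction closes the
   preceding utterance is not fully determined by the rule statement, and
   this reading is the package's interpretation.
3. Break whenever the silent **pause** after a token exceeds 2,000 ms.
   The threshold is strict: a pause of exactly 2,000 ms ("two seconds")
   does not split, only *more than* two seconds does.
4. After a **conjunctive suffix** (e.g. *-ko*), break at the first
   subsequent intonation shift or over-threshold pause; with neither,
   break after the second conjunctive suffix. The suffix count restarts at
   every utterance boundary, reading "extends to the second conjunctive
   suffix" as a within-utterance limit.

When rules coincide at one junction, the pause rule dominates the
sentence-ending rule, which dominates the suffix rule. The only observable
consequence is that an over-threshold pause overrides the
contextual-connection exception of rule 1 — the pause rule is stated
unconditionally. Intonation shifts are input flags; no acoustic analysis
is performed.

The engine is checked property-style against an independently written
brute-force scanner on a thousand random marker streams, and satisfies
token conservation (flattening the output reproduces the input),
idempotence, and pause-threshold monotonicity.

## Linguistic measures

With `word_count` the number of intelligible tokens and `ciu_count` the
number of CIU-flagged tokens (validated upstream as a subset),

* CIUs/min `= ciu_count * 60000 / task_duration_ms`,
* WPM `= word_count * 60000 / task_duration_ms`.

Noun/verb tallies are restricted to intelligible tokens so that the
productivity and word-count universes agree; non-word fillers are `other`
tokens with `intelligible = FALSE` and never enter any count. Type counts
are keyed on the **lemma** by default (configurable to surface forms):
Korean inflection would otherwise multiply surface variants of one word
into spurious types. Whether the original tallies were lemma- or
surface-based is not stated in the source conventions; lemma-based is this
package's choice. Per-utterance normalisation divides by the trial's
utterance count, so duplicating every utterance leaves the per-utterance
values unchanged.

## AOI geometry and fixation assignment

Each picture carries 12 AOI polygons: 9 active agents (people/animals) and
3 static objects for the Han River picture, 6 and 6 for the Beach picture.
The published material lists the AOI labels and roles but not the freehand
polygon coordinates, so the packaged configurations
(`inst/extdata/aoi_*_synthetic.yaml`) carry **synthetic** polygons laid
out on a 4 x 3 grid of the screen — faithful in number, label and role,
synthetic in shape. Any real deployment should supply its own polygons via
`read_aoi_config()`.

`assign_fixations()` labels a fixation with the first configured region
containing its gaze point. Membership counts the boundary as inside and
supports a uniform outward buffer (in px): a point belongs to the buffered
region iff it is inside the polygon or within `buffer_px` of its boundary,
which is exactly the membership test of the Minkowski-sum outward buffer.
This mirrors the original buffered freehand AOIs drawn slightly larger
than their targets; the packaged synthetic polygons are already drawn
generously, so the default buffer is 0. Off-screen fixations are flagged
and left unlabeled, never dropped.

## Pre-speech fixation statistics

For utterance *i* with onset `t_i`, the pre-speech window is
`[t_{i-1}, t_i)`; for the first utterance it is `[0, t_1)`, extending the
same logic to picture onset, since the first description is planned from
stimulus onset. Windows are half-open so that consecutive windows tile
`[0, t_n)` exactly and a fixation starting at an utterance onset belongs
to the next window.

A fixation is credited to utterance *i* when its *onset* lies in the
window and its AOI label equals the utterance's AOI label. The full
fixation duration is credited by default (`duration_mode = "onset"`),
treating fixations as atomic events as in Data-Viewer-style reports;
whether durations straddling a window edge should be clipped is not
determined by the source definition, so a `"truncate"` mode is provided.
When several consecutive utterances target the same AOI, each utterance
gets its own window under the same rule — also an interpretation, as the
definition is silent on interleaved repeats.

Utterances without an AOI label (personal commentary such as "this
reminds me of my vacation") contribute neither counts nor denominator;
with no AOI-related utterances at all the aggregates are reported missing,
not zero. The implementation is verified against a quadratic
utterance-by-fixation oracle on hundreds of random trials and is invariant
to global time shifts and to deletion of fixations on unrelated AOIs.

## Mixed-design ANOVA

`mixed_anova()` fits the univariate split-plot decomposition via
`stats::aov()` with an `Error(subject/within)` term: the between-group
effect is tested against subjects-within-groups; each within effect and
its group interaction against the corresponding factor x subject(group)
stratum. With 24 + 22 subjects every reported effect has df (1, 44). All
factors are two-level, so sphericity corrections are moot and omitted.
Sums of squares are sequential within strata; with a single between
factor and complete two-level within factors the only place weighting
matters under unequal group sizes is the within main effects, where the
sequential (sample-weighted) decomposition is used — a difference from
unweighted-means software output only in the presence of a group
imbalance *and* a true interaction, and immaterial under the null.
Degenerate inputs (constant dependent variable) return zero sums of
squares with missing F, after flooring sums of squares below
`1e-10 * sum(y^2)` to absorb floating-point residue.

Partial eta squared uses each effect's own error stratum,
`SS_eff / (SS_eff + SS_err)`, equal to `F·df1 / (F·df1 + df2)` for
single-df effects (`partial_eta_from_F()`). The implementation is checked
against a closed-form balanced cell-means oracle, against the identity
`F_group = t²` on subject means, against an exact sum-of-squares
partition, and by a 2,000-replicate null simulation whose rejection rates
must stay within [0.03, 0.07] at the 0.05 level with uniform p-values.

`two_sample_t()` exposes both pooled (`df = n1 + n2 - 2`) and Welch
degrees of freedom, since reports mix both styles; no variance-equality
test is used to choose between them.

## The synthetic cohort generator

The participant-level data of the motivating study are not publicly
available, so `generate_cohort()` produces a synthetic stand-in with the
structure the analysis assumes: 24 younger and 22 older participants, each
describing both pictures.

Timing uses lognormal utterance durations (median 3 s, log-SD 0.35) and
exponential inter-utterance gaps (mean 0.8 s) — positive and right-skewed,
the standard shape for speech timing. The Han River picture yields more
utterances on average (16 vs 12) as the richer scene. Tokens are synthetic
lemmas drawn from a closed per-AOI vocabulary with Poisson class counts;
no natural language is generated. Utterance-final tokens carry
sentence-ending particles and within-utterance pauses stay below
threshold, so the rule engine reproduces the generated boundaries — a
cross-module consistency check exercised in the tests.

Gaze is coupled to speech through the **eye-voice span**: each AOI-related
utterance is preceded by a primary fixation inside its target AOI starting
about one span (default mean 1,000 ms, the canonical near-one-second lag)
before the utterance onset and ending ~150 ms before speech. Extra
pre-speech fixations arrive at a Poisson rate, and background fixations at
uniformly random screen positions fill the task at 0.8/s. When a window is
narrower than the drawn span the span is resampled and finally clamped,
with a warning counter — never silently invalid.

Group and picture effects are switches; with all switches off the two
groups share one generating distribution exactly. Directions default to
the reported ageing pattern: older adults get lower CIU probability
(0.64 vs 0.76), lower noun/verb emission (-0.5/-0.4 tokens per
utterance class), a 300 ms longer eye-voice span (hence longer pre-speech
durations), and — only on the Han River picture — an extra pre-speech
fixation rate (+0.7), producing the count interaction. No cell means or
SDs are published for any measure, so these magnitudes are the package's
own calibration, chosen once to give standardized group differences of
roughly one between-subject SD, the order implied by the reported effect
sizes (partial eta squared ~ 0.1-0.4); they are free parameters of
`cohort_config()`, not estimates of the real data.

`recovery_experiment()` closes the loop: generate, score, test, and report
per-effect rejection rates and recovered signs. At the defaults, 30
replicates give power 1.0 for all five configured effects with every sign
recovered; with switches off it estimates the pipeline-level type-I rate.

### What the generator does and does not emulate

It reproduces the data *structure* (two-level factors, within-subject
crossing, annotation schema, gaze-speech coupling, between-subject
heterogeneity) but not the texture of real data: fixations may overlap in
time (real fixation parsers emit disjoint events), token annotation noise
and coder disagreement are absent, vocabulary is closed, and background
gaze is uniform rather than scene-driven. Passing tests therefore certify
the pipeline's arithmetic and inferential calibration, not distributional
realism of speech or gaze.

## Numerical and design choices

* Times are integer milliseconds on a per-trial clock (picture onset = 0);
  1,000 Hz sampling makes milliseconds exact.
* Pixels use the screen convention: origin top-left, x rightward,
  y downward.
* Unparseable rows and invariant violations fail loudly with their
  location; nothing is silently skipped, because every denominator
  (minutes, utterances, AOI-related utterances) depends on completeness.
* Utterance indices are 1-based, following R convention.
* Problem sizes in the test suite (e.g. 1,000 segmentation streams, 500
  gaze trials, 2,000 ANOVA null replicates, 30 recovery replicates) were
  chosen to bound Monte-Carlo error well below the asserted margins.

## Known limitations

* The ANOVA layer covers the study's 2 x 2 (x 2) designs only; factors
  with more than two levels, post-hoc tests and random-slope mixed models
  are out of scope.
* Korean morphological analysis, forced alignment and speech recognition
  are out of scope by design: annotations are inputs.
* The packaged AOI polygons are synthetic stand-ins; conclusions about
  real gaze data require the original (or re-drawn) AOI outlines.
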