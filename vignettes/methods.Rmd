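---
title: "Methods: consistency screening and the Mantel structure score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consistency screening and the Mantel structure score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette records the scientific and numerical decisions behind the
package: the models implemented, the defaults and why they were chosen,
what the synthetic-data generator does and does not emulate, and the
known limitations.

## The data model

A trial is one response: a participant, a task (`vowel` with 16 items or
`grapheme` with 36), an item, a repetition index 1–3, and either an
integer RGB triple or an explicit no-color flag. No-color is never encoded
as `(0,0,0)` — black is a legitimate color choice — and the validator
rejects files that blur the two. One schema serves measured and simulated
data, so everything the generator emits passes the same validation as
real logs.

## Color spaces

Device RGB is interpreted as sRGB (IEC 61966-2-1): gamma companding,
illuminant D65, 2° observer. The data this package targets come from
browser color pickers, for which sRGB is the operative standard; no other
working space is supported, and no chromatic adaptation beyond the fixed
D65 white is applied. The conversion constants are derived
self-consistently: the linear-RGB-to-XYZ matrix is the IEC one, and the
reference white is the image of RGB (1,1,1) under that matrix —
Xn = 95.0470, Yn = 100.0000, Zn = 108.8830 — so white maps to L = 100,
u = v = a = b = 0 *exactly*, and black's undefined chromaticity is pinned
to the white point so that u = v = 0 there too.

A caveat worth recording: published color libraries round these constants
differently (matrix precision, white point), and consequently disagree
with one another at roughly the 1e-2 level per Lab/Luv coordinate for
saturated colors. Our unit tests therefore check the gray axis and white
point to 1e-4 or better, but cross-library agreement (against farver) only
to 0.02 absolute per coordinate. CIEDE2000 has no such ambiguity: the
implementation reproduces the standard 34-pair verification dataset to
four decimals.

Consistency uses CIELuv (Euclidean distances), the structure score uses
CIELab (CIEDE2000 distances). The two spaces share the L axis exactly;
tests assert this. CIEDE2000's triangle inequality failures are a known
property of the formula, so no test asserts metric triangle behavior —
only symmetry, nonnegativity, and identity of indiscernibles.

## Consistency scoring and classification

Per item, `d` is the sum of the three pairwise CIELuv distances between
the repeated responses; the participant's score `c` is the mean of `d`
over valid items. Decisions the source procedure leaves open, fixed here:

- **Item validity.** `d` needs all three trials; any no-color trial
  invalidates the whole item rather than imputing or using partial pairs,
  because a two-trial `d` would not be commensurable with three-pair sums.
- **Exclusion.** A participant is excluded when invalid items exceed half
  the task's item count (strictly more than half); exactly half is
  retained. A participant with zero valid items is always excluded.
- **Cutoff.** Classification is strictly `c < 135.3` (default); a score
  exactly at the cutoff is a nonsynesthete. The grapheme task reuses the
  same cutoff by default but it is configurable, since the cutoff was
  originally derived on a 36-item grapheme battery and is plausibly
  easier to pass with 16 items.

## Phoneme categorization

A stimulus is assigned to the nearest inventory phoneme by Euclidean
distance in raw Hz — deliberately unnormalized, matching the procedure
this implements; per-axis z-scoring is available behind a flag (off by
default) for users whose inventories span very different F1/F2 scales.
Nearest-neighbor assignment is identical to Voronoi cell membership, and
the tests verify it against an exhaustive argmin and an independent 1-NN
classifier. Ties (measure-zero with real formants) break deterministically
to the earliest inventory row. Downstream, the *canonical* coordinates of
the assigned phoneme — not the stimulus's raw formants — feed the
structure score, so stimuli in one cell collapse onto one point. That
categorical collapse is intentional: it encodes the claim that perception
of the stimuli is categorical.

The packaged inventory (12 Dutch-style monophthongs) and 16-point stimulus
table are synthetic placeholders with plausible adult formant values; they
are clearly labeled as such and meant to be replaced by measured tables
for real analyses. All tests build their own synthetic inventories.

## The structure score

For one participant with n colored responses, two n×n distance matrices
are built: vowel distances (Euclidean, canonical F1–F2; zero for same-item
pairs) and color distances (CIEDE2000 in Lab). The veridical statistic is
the Pearson correlation of the strict upper triangles (the Mantel
statistic). The null model shuffles responses within each item and then
reassigns whole per-item response sets across items by a random bijection
of item labels.

Decisions made where the wording of the procedure admits alternatives:

- **Permutation unit.** Per-item response *sets* move across items as
  units. This preserves each participant's within-item consistency under
  the null, so the test isolates *cross-item* structure rather than
  punishing mere repetition stability. The alternative reading — shuffling
  individual responses across items — is available via
  `unit = "response"`.
- **Within-item shuffle.** Retained for fidelity, but provably inert
  under the set-unit scheme: same-item vowel distances are all zero and
  color values travel with their responses, so only the across-item
  relabeling changes the correlation. `structure_score()` exploits this
  (each permutation reduces to indexing a precomputed item-level distance
  matrix); a test asserts the equivalence against the literal shuffle.
- **Sidedness.** p is one-sided in r (more structured = larger r),
  matching the question "how often is a random mapping *more* structured
  than the real one"; it uses add-one smoothing,
  p = (1 + #{r_perm ≥ r}) / (1 + n_perm), so p is never zero from a
  finite sample, and ties count against significance.
- **Degeneracy.** If either distance vector has zero variance (one color
  for everything, or responses to a single item), or the permutation
  distribution collapses, the result is flagged degenerate with z = 0 and
  p = 1 rather than erroring: such responders (e.g., constant-color
  participants who nevertheless pass the consistency screen) are
  substantively interesting and must survive the pipeline.
- **No-color handling.** No-color responses are dropped before the
  matrices are built (at least 3 colored responses required). Dropping is
  the only option that leaves both matrices well-defined.
- **Seeds.** One integer seed governs the whole permutation stream;
  cohort runs derive per-participant seeds as `seed + participant index`,
  so results are reproducible participant-by-participant and could be
  parallelized without stream collisions.

Default `n_perm` is 10,000. Tests and the acceptance script use 199–999
permutations, which keeps the full suite within a few minutes on one CPU
while leaving the p-value granularity (1/200 to 1/1000) fine enough for
the 5% significance checks; these sizes are the package's chosen test
conditions, and the add-one p-value is exact at any `n_perm`.

## The synthetic-data generator

Each simulated participant draws a per-item color *anchor* in Lab as a
mixture `alpha * structured + (1 - alpha) * random`, plus per-item
Gaussian jitter (sd `item_jitter`); each trial adds per-trial Gaussian
jitter (sd `trial_jitter`), converts to integer RGB with gamut clipping,
and becomes no-color with probability `no_color_rate`. The structured map
is an affine image of canonical F1–F2 space with positive F2 loadings on
L and b and a positive F1 loading on a — front/high vowels come out
lighter and yellower, low vowels redder, the directionality reported for
real cohorts; the exact coefficients are plumbing, chosen to span most of
the gamut, not science.

Archetypes and calibration. Cohorts mix three archetypes:
`synesthete-like` (high alpha, low jitter), `nonsynesthete-like`
(moderate alpha, high jitter) and `degenerate` (one constant color for
every item and trial — the false-positive archetype for the consistency
screen). Each participant's parameters are drawn from within-archetype
ranges; the ranges were calibrated, once, against four published cohort
facts: group mean consistency near 96 (synesthetes) and 224
(nonsynesthetes), a cohort synesthete rate near 30%, a structured-mapping
rate near 70%, and a no-color rate of 4% ("less than 5% of trials").
The fixed-parameter constructors (`synesthete_profile()`, trial jitter
11.8; `nonsynesthete_profile()`, trial jitter 39) are the archetype modes
and serve single-participant simulations and tests. Notably, the
nonsynesthete archetype is *not* unstructured: its alpha range
(0.5–0.95) makes a majority of nonsynesthete-like participants
significantly structured despite their inconsistency, which is exactly
the dissociation the structure score exists to measure. Archetype counts
in a cohort are apportioned deterministically (largest remainder), so a
30% mixture is exactly 30% of participants.

What the generator does **not** emulate: real response noise is not
isotropic Gaussian in Lab (people err along hue and lightness
differently); real populations are a continuum, not a two-archetype
mixture, so cohort-level statistics that depend on within-group spread —
the magnitude of the structure/consistency correlation, the group-t — come
out stronger in simulation than in measured data, and only their signs
and orderings should be read as predictions; extreme trial jitter
interacts with gamut clipping, biasing realized jitter downward near the
cube faces; and no grapheme-shape, ordinality, or learning effects exist
in the model. Passing tests on synthetic cohorts therefore demonstrate
that the *machinery* recovers known ground truth, not that real cohorts
look like the simulation.

## Verification design

The test suite pairs every computational path with an independent oracle:
CIEDE2000 against the published 34-pair verification set and farver;
conversions against farver (with the constant-rounding caveat above);
nearest-phoneme against exhaustive argmin and `class::knn1`; the Mantel
statistic against a closed-form Pearson computation and `vegan::mantel`;
the permutation distribution against exhaustive enumeration of all 3!
reassignments on a three-item case; and the end-to-end pipeline against
generator ground truth (null calibration of the rejection rate at
alpha = 0, 100% detection of noise-free isomorphic mappings, monotone
parameter recovery along jitter and structure-strength grids, and mixture
recovery on a 1,000-participant cohort).

## Known limitations

- The consistency cutoff is inherited, not re-derived; with 16 items it
  may admit false positives (the degenerate archetype exercises this).
- Canonical-coordinate collapse makes the vowel distance matrix blind to
  within-cell stimulus differences by design; users wanting raw-formant
  distances can pass their own coordinate table.
- CIEDE2000 is not a metric; downstream consumers should not assume
  triangle inequalities over color distances.
- The permutation test is one-sided; systematically *anti*-structured
  mappings (r far below the null) are reported with large p, visible only
  through negative z.
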