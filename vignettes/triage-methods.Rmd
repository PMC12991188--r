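---
title: "Methods: rule-based ophthalmic triage and its desk-scale evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based ophthalmic triage and its desk-scale evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eyetriage)
```

## The triage model

`eyetriage` models symptom-based triage as three strictly separated,
declarative stages.

**Questionnaire.** A branching multiple-choice questionnaire is a
directed acyclic graph. Each question has at least two options; each
option may assert controlled-vocabulary *symptom codes* and at most one
trauma flag (`chemical`, `blunt`, `high_velocity`). Conditional edges
(`any_of` predicates over the chosen options of the source question,
first declared match wins, mandatory default edge) route the patient to
the next question or to the terminal state. Load-time validation makes
traversal total: acyclicity, reachability of every question, a default
edge everywhere, and a hard cap of 25 questions on every path are all
checked before a graph is accepted, so any answer sequence terminates.
The entry question is the complaint filter with four categories: red
and/or painful eye, painless visual disturbance, eyelid problems, eye
injury.

**Acuity rating.** A symptom acuity table maps code sets to an ordinal
acuity scale with five levels, most to least acute: same-day emergency,
within 24 h, within 48 h, within a week/routine, self-care. Triggers
are conjunctions (`all_of`) optionally combined with a disjunction
(`any_of`). Both combinators are *monotone*: adding symptoms can only
add rule firings, never remove them, which gives the safety-critical
property that extra reported symptoms never lower the urgency.

**Disposition.** The disposition urgency is the maximum acuity over
fired rules (self-care when nothing fires), and the service comes from
the maximal rules' hints with band defaults (emergency → hospital
emergency eye services; 24 h → community urgent eyecare; 48 h and
routine → community optometry; self-care → pharmacist). Two aspects are
deliberately hard-wired for safety and determinism: a trauma flag
always short-circuits to a same-day hospital disposition with a
first-aid notice (the fast-path), and conflicting service hints at the
same maximal level resolve by the fixed precedence ED/EEC > MECS/CUES >
community optometry > pharmacist, with a logged message.

The questionnaire and rule table shipped under `inst/extdata/` are
*representative fixtures*, not reproductions of any proprietary
instrument: the engine is content-agnostic and treats both documents as
data. The fixture vocabulary (21 codes) and rule set (19 rules) were
chosen to span all five acuity levels within each of the structures the
four complaint categories admit, with three emergency presentations
(sudden painless visual loss, painful red eye with nausea/halos, lid
swelling with systemic upset) plus the trauma fast-path.

### Design choices that were genuinely open

* **Multi-select.** Whether symptom checklists allow multiple
  selections per question is an instrument-level choice; the engine
  supports both (`select: single | multiple`), the filter question is
  single-select, and the shipped checklists are multi-select.
* **Edge tie-breaking.** First matching edge in declaration order wins
  and every question must declare a default edge. This makes traversal
  a total function of the transcript, at the cost of making edge order
  semantically significant.
* **Timestamps.** Sessions never read the wall clock internally; start
  and finish times are injected by the caller, which is what makes
  duration logic exactly testable.
* **Telephone completion** is a session attribute only (the
  receptionist keys in the same questionnaire), not a separate flow.
* **Masking** is implemented at report level: the masked report is the
  unmasked report with exactly the disposition block removed, so a
  field-level diff proves that masking leaks nothing and withholds
  nothing else.

## Evaluation statistics

Urgency is dichotomized at the 24-hour boundary: the two most acute
levels count as "urgent". The gold standard is adjudicated from two
reviewers with a casting vote on disagreements; both triage arms are
scored against the *same* adjudicated vector.

* **Paired accuracy comparison.** Sensitivities of two arms are
  compared by the continuity-corrected McNemar statistic
  $(|b-c|-1)^2/(b+c)$ on the discordant pairs among gold-positives
  (specificities: among gold-negatives), referred to $\chi^2_1$. Two
  numerical conventions are logged at run time: $b+c=0$ returns
  statistic 0 and $p=1$; and when $b=c$ the formula gives $1/(b+c)$,
  whereas `stats::mcnemar.test` zeroes the corrected difference — this
  package follows the closed form as stated, and the test suite
  cross-checks against the reference implementation away from that
  boundary.
* **Cohen's kappa** uses the marginal-chance correction with the
  Fleiss–Cohen–Everitt large-sample standard error for the 95% CI
  (the CI method is a package choice — swappable — since asymptotic and
  bootstrap intervals both have currency). Interpretation bands follow
  the a-priori cut-points: ≤0 none; ≤0.20 none-to-slight; ≤0.40 fair;
  ≤0.60 moderate; ≤0.80 substantial; ≤1.00 almost perfect. Kappa is an
  error (not `NaN`) when both raters are constant and identical.
* **Mann–Whitney U** is computed from midranks (ties count ½). The
  p-value is exact (`pwilcox`) when both groups have ≤ 20 observations
  and no ties, else a tie-corrected normal approximation with
  continuity correction — the usual small/large-sample split.
* **Odds ratios** use the Woolf log-scale interval, with the
  Haldane–Anscombe 0.5 correction on any zero cell (logged).
* Sensitivity or specificity with an empty class is an explicit
  `undefined_metric` error rather than a silent 0; display rounding is
  one decimal for percentages and two for kappa, with internal values
  unrounded.

## What the synthetic cohort emulates — and what it does not

The generator reproduces the *structure* of a community evaluation
cohort: four complaint categories at weights 95:82:22:12; a 25% target
prevalence of truly urgent presentations (archetypes are drawn
urgent-band vs not, so the target is exact in expectation regardless of
category mix); integer ages from a truncated normal (mean 53.5 y,
SD 17.5, bounds 13–90, sampled by inverse CDF); telephone completion
with probability 19/136; lognormal questionnaire durations (median
≈ 4.6 min) bounded to 1.5–16 min; and voluntary 5-point Likert feedback
(response probability 147/209, top-2 probability 0.82 among
respondents, within-band splits fixed to give a mean near 4.3). Answer
noise resamples each visited choice with a given per-question
probability to a *different* admissible choice and re-walks the graph,
so perturbed scripts are always valid traversals and a noise rate of 1
changes every visited answer.

Observers are simulated with independent sensitivity/specificity error
models against ground truth. The defaults were fixed once from the
scenario being emulated: the optometry triager at sensitivity 0.77 and
specificity 0.80, and both expert reviewers (and the casting-vote
clinician) at sensitivity = specificity = 0.85, a value chosen because
at 25% prevalence it gives a between-reviewer kappa of ≈ 0.42 by the
closed form — i.e. the "moderate at best" expert agreement such studies
report — and because symptom-report review plausibly errs in both
directions. These are structural emulation targets, not fitted
parameters.

Two consequences matter for interpreting recovery experiments:

* With *noisy* reviewers the adjudicated gold standard is itself
  imperfect, so accuracy measured against it is attenuated relative to
  the generating parameters (analytically, a 0.77-sensitivity triager
  measures ≈ 0.68 against the default adjudicated standard). The
  parameter-recovery check therefore uses perfect reviewers — gold
  standard equal to expert truth — to verify that the evaluation
  pipeline recovers the triager's generating sensitivity/specificity,
  while the between-reviewer kappa ≈ 0.4 property is verified
  separately under the default noisy-reviewer model. Attenuation by an
  imperfect reference is a real phenomenon, not an artifact, and is
  worth keeping visible.
* Reviewers are conditioned on the archetype's ground truth, not on the
  (possibly noise-perturbed) report content, so answer noise degrades
  the tool arm without degrading the gold standard.

The generator does **not** model patient compliance, appointment
availability, practice-level clustering, patient anxiety or
communication effects (mechanisms that can drive human triage toward
caution), missing-mode records by default (a `mode_missing_rate`
parameter exists, default 0), or non-English administration. Passing
tests on synthetic cohorts therefore demonstrate that the *pipeline* is
correct and calibrated under its stated error models — not that any
particular instrument achieves these accuracies in the field.

Truth columns (`true_archetype`, `true_level`, `true_urgent`) are kept
at the end of the cohort table, and the evaluation functions read only
the observed columns; a test scrambles the truth columns and verifies
the evaluation output is unchanged.

## Problem sizes and numerical tolerances

The test suite exhausts small spaces where exhaustion is the right
oracle: all confusion-count compositions up to n = 12 (every binary
label configuration up to permutation, since the metrics are
permutation-invariant) against brute-force recomputation; all binary
Mann–Whitney score configurations up to group sizes 12 × 6 against
pairwise enumeration; the full discordant-count grid to 25 × 25 for
McNemar (statistic to machine precision, tail against numerical
integration at 1e-10); all 32 subsets of a 5-code vocabulary for
trigger monotonicity; and every path of the shipped questionnaire.
Stochastic properties use fixed seeds: 10,000 random sessions for
urgency monotonicity and fast-path dominance, 10,000 independent
labeler pairs at n = 200 for the centering of kappa (|mean| < 0.02),
and cohorts of n = 5000 for parameter recovery within ±0.03 — sizes at
which Monte-Carlo error is comfortably inside the asserted tolerances
while the whole suite runs in a couple of minutes on one CPU.

## Known limitations

* The shipped questionnaire and acuity table are illustrative: clinical
  deployment would substitute validated content files, which the loader
  verifies structurally but cannot verify clinically.
* The acuity table's coverage check guarantees every symptom code can
  fire *some* rule, not that the rule set is clinically complete.
* The kappa CI is asymptotic; at very small n or extreme marginals a
  bootstrap would be preferable.
* The simulator's independence assumptions (between raters, between
  patients) are conservative; correlated reviewer errors would lower
  effective gold-standard quality further than modeled.
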