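---
title: "Measuring the SDOH documentation gap with rule-based note search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the SDOH documentation gap with rule-based note search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdohscan)
```

## The problem and the model

Structured EHR fields under-report social determinants of health: coding an
ICD-10-CM Z code for food insecurity or social isolation takes extra
clinician effort, while the same information flows naturally into the
narrative of a progress note. `sdohscan` quantifies this gap for a
primary-care diabetes cohort by classifying every patient twice — once from
diagnosis codes, once from free-text notes — and comparing per-domain
prevalences.

The narrative classifier is deliberately not a statistical model. Each of
the seven SDOH domains (social connections/isolation, employment, housing,
food, education, finance, stress) is covered by a single human-curated
Boolean query, so every positive can be traced to a concrete span of text
and audited by a chart reviewer. The price of that transparency is a
substantial false-positive rate ("unemployed son", "volunteers at the
animal shelter"), which is why the validation statistics — PPV against
manual review, and two-reviewer agreement — are part of the pipeline rather
than an afterthought.

## The query dialect and its semantics

A rule is `INCLUDE` or `INCLUDE NOT EXCLUDE`, where each side is a
parenthesised `OR`/`AND` composition of:

* quoted phrases, optionally with a proximity suffix: `"social isolation"~10`;
* bare terms, optionally with a trailing wildcard: `unemploy*`;
* commas between phrases, read as `OR` (the only reading that makes the
  published finance rule well-formed).

Matching operates on a normalized token stream: curly quotes become ASCII,
case folds to lower, tokens are maximal runs of letters/digits with
internal apostrophes kept (`doesn't`), and every other character is a
separator. Digit runs are tokens so that numeric exclusions such as
`"isolation 14"~6` can match.

Three semantic choices deserve explicit statement:

* **Slop.** A phrase with $k$ terms and slop $s$ matches every *minimal*
  token window of length $\le k+s$ containing all $k$ terms on distinct
  tokens, in any order when $s>0$ and adjacent-in-order when $s=0$. Full
  Lucene edit-count slop semantics are not publicly pinned down; this
  containment definition is deterministic, brute-force verifiable (the test
  suite checks it against exhaustive window enumeration on 10,000 random
  instances), and reproduces the behaviour of all published example
  snippets. An ordinal suffix (`~10th`) is read as `~10`; the trailing
  "th" is a display artifact of the source system, and no other coherent
  reading exists.
* **Document-level NOT.** One exclusion hit anywhere in a note vetoes that
  note for the rule, mirroring Boolean NOT over documents in a search
  engine. This is the package's only negation handling; there is no
  general negation or uncertainty detector, and no section segmentation.
* **Deduplication.** Duplicate disjuncts (the published finance rule lists
  "financial difficulty" twice, the stress NOT-list "myocardial" twice)
  are removed at parse time; semantics are unchanged.

One consequence of punctuation-stripping worth knowing: the food rule's
exclusion entry `"Food insecure?"` tokenizes identically to its include
phrase `"food insecure"`, so that include phrase can never produce a
positive note — any note matching it also matches the exclusion. The
package keeps the rule faithful to its published text rather than patching
it; the snippet bank (below) therefore verifies each generated template
against its rule and drops self-vetoing ones.

## Aggregation and cohort rules

The unit of matching is the note; a patient is domain-positive iff at least
one note of an eligible type (progress note, telephone encounter, history &
physical, assessment & plan; configurable) is positive. Patients with no
notes are reported explicitly rather than silently counted negative. The
structured arm matches codes hierarchically: a record counts toward a
domain when its normalized code equals or extends a listed stem, so
unlisted children (Z59.00) count toward their parent (Z59.0). The
social-connections grouping uses the three listed subcodes (Z60.2, Z60.4,
Z60.8) by default; `sdoh_code_map(widen_z60 = TRUE)` widens it to the whole
Z60 category, an ambiguity the published groupings leave open.

Cohort selection requires, within the study window (default
2018-01-01..2019-12-31), two *completed* primary-care encounters on
distinct dates of service and one E10/E11 diagnosis. Age filtering applies
only when an age table is supplied — synthetic cohorts omit birth dates —
and its absence is logged.

## Validation statistics

* **PPV** = confirmed/flagged, with a 95% Wilson score interval (well
  behaved at the small per-domain counts a 10% review sample produces; the
  published analysis reported no intervals, so the choice is the
  package's).
* **Observed proportional agreement** $p_o$ and **Cohen kappa**
  $(p_o-p_e)/(1-p_e)$ with $p_e$ from the reviewers' marginals. When both
  reviewers are constant and equal, $p_e=1$ and kappa is reported as
  *undefined* — not 0 or 1 — the standard convention, relevant here because
  near-degenerate domains occur in small review samples.
* **Review sampling** draws `ceiling(fraction * n)` notes per domain
  without replacement, so small domains always contribute at least one
  note; the sample is a pure function of the seed, and sampling restores
  the caller's RNG state. The agreement unit is the clinical note (a
  patient-level mode exists via patient-keyed label tables); kappa is
  computed on the cross-review sample rather than the full single-reviewer
  pass, whose denominator the two-step review design leaves ambiguous.

Sensitivity and specificity are deliberately absent for real data: notes
the rules did not flag are never reviewed, so recall is unknowable there.
They are computable on synthetic data only because ground truth is planted.

## What the synthetic generator emulates

`generate_cohort()` draws, per patient and domain, a latent true-case
indicator with probability `true_prevalence[d]`; a true case receives a Z
code with probability `structured_doc_rate` (default 0.10) and a narrative
true-positive snippet with probability `narrative_doc_rate` (default
0.80). Defaults for `true_prevalence` (0.0103–0.0648 across domains) were
set once so the products land where published cohorts put them — coded
prevalence around 0.1–0.7%, narrative-confirmed prevalence around
0.8–5.2% — and are not tuned thereafter. Notes per patient are Poisson with
mean 7, echoing a ~30,000-note/4300-patient corpus; note types are drawn
mostly from the four eligible categories with a 10% "other" share.

Confusable snippets (the published false-positive terminologies, e.g.
"Food insecurity: none") are planted per patient-domain with probability
`fp_snippet_rate` (0.02), and exclusion-protected negation snippets (built
from rule NOT-lists) in non-cases with probability `negation_rate` (0.02).
Reviewer behaviour is simulated as ground truth with independent per-label
flips at `reviewer_error_rate` (0.02, giving expected agreement
$(1-e)^2+e^2 \approx 0.96$, the order of published reviewer agreement).

Three constructions make the planted-evidence properties exact rather than
probabilistic:

* filler text comes from a vocabulary filtered to share no token with any
  rule (and no prefix of any wildcard stem), so filler can neither create
  nor veto a match;
* at most one snippet is planted per note — a snippet for one domain may
  contain another domain's exclusion token (finance's bare `none` appears
  in the food confusable), and co-locating them could veto a planted true
  positive;
* a snippet needing a home when the patient has no unoccupied eligible
  note gets a fresh note appended, slightly widening the note-count
  distribution but keeping documentation rates exactly Bernoulli.

What the generator does **not** emulate: real clinical prose, section
structure, copy-forwarded text, correlated SDOH domains, temporality, or
de-identification artifacts. Passing tests on synthetic data therefore
demonstrate that the machinery is correct under the stated statistical
structure, not that the rules generalize to any particular health system's
notes — that is what the chart-review PPVs are for.

## Numerical and presentation choices

* Percentages print half-up at 2 decimals (prevalence) and 1 decimal
  (PPV), matching the conventions of published prevalence tables; R's
  banker's rounding would differ at midpoints.
* The comparison's unstructured column counts review-confirmed patients
  when labels are supplied and raw rule-positive patients otherwise; the
  mode is stamped on the result object, since published prevalence tables
  report the confirmed counts while overlap totals use raw counts.
* Empty or whitespace-only notes are negative, not errors; EHR extracts
  contain them.
* Parse errors report the character offset; `NOT` is accepted only once,
  at the top level, which is the shape of every published rule.
* Minimal-window reporting deduplicates overlapping proximity hits; the
  spans exported for review (`term@start-end`, 0-based token positions)
  are exactly the include-side matches of positive notes.

## Problem sizes

The test suite exercises the proximity engine against an exhaustive oracle
on 10,400 random instances (token sequences up to length 30, slop up to
10), and the end-to-end property checks run on seeded synthetic cohorts of
120–2000 patients, sizes at which every configured rate is resolvable
within three binomial standard errors while the whole suite stays fast.
The acceptance script's synthetic stage uses 2000 patients.

## Known limitations

* The rules are verbatim artifacts of one health system's curation; their
  PPVs elsewhere are an empirical question.
* Wildcards are prefix-only and phrase-internal wildcards are unsupported
  (none occur in the shipped rules).
* Structured-arm comparisons use ICD-10-CM Z codes only; LOINC/SNOMED/CPT
  social-risk codes are out of scope.
* The match engine treats every note independently; duplicated
  (copy-forwarded) text inflates note-level counts, though patient-level
  flags are unaffected.
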