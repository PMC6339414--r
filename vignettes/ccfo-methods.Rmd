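---
title: "Methods: the CCFO data model, extraction rules, and scoring engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the CCFO data model, extraction rules, and scoring engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccfo)
```

## The model

`ccfo` treats a clinical note as textual evidence of *findings* — conclusions
a clinician recorded, not direct measurements of the patient's body. The
ontology distinguishes three things that are often conflated:

* a **concept** (e.g. *bed-ridden finding*, CCFOID 1121221), a node in a
  hierarchy rooted at *clinical finding*, optionally annotated with a
  SNOMED-CT id where the mapping is exact;
* a **term** (e.g. "stretcher"), a surface string whose presence suggests the
  author was thinking of a concept — deliberately *not* a synonym; and
* a **qualifier value**, a modifier on one of three axes: ability
  (able / with difficulty / unable), frequency (high / mid / absent), and
  course (chronic / short-duration / sudden-onset). Twelve qualifier-value
  concepts (nine levels plus three axis roots) live under their own root.

Scored concept-qualifier pairings carry a Rockwood clinical-frailty rating
(1 = very fit to 9 = terminally ill, averaged across raters and kept
fractional — 7.44 stays 7.44), plus low/medium/high ratings for
cardiac-intervention fix-ability and relevance. Rater disagreements are kept
verbatim as tie codes ("TIED L+H") rather than collapsed; `concept_relevance()`
derives a `cardiac_specific` flag only when both ratings are unambiguously
high.

### Fixtures and identifiers

The fixture of record is plain TSV (one row per concept, term, and score
record): easy to diff, easy to test. OWL (RDF/XML) is an import/export
dialect around the same model, not the internal representation. CCFOIDs are
prefix-structured but treated as opaque strings; the hierarchy comes from the
explicit `parent_id` column only.

The published CCFO id assignments contain three collisions (131 is printed
for both dyspnea-on-exertion and comorbid-condition-count; 11271 for both
incontinence and continence; 11241 for community-living activities and
driving). The fixture keeps the id with the stronger structural claim on each
and reassigns the other to a free slot (1325, 11272, 112411). "supine" is
printed both as a bed-ridden term and as a removed ambiguous term; the
fixture keeps it excluded, and `validate_ontology()` reports any
term/exclusion conflict as a violation.

### The synthetic full fixture

The core fixture ships only individually documented content. The full
156-concept release is reconstructed synthetically by
`synthetic_full_ontology()`: clearly labelled padding concepts and terms are
added deterministically until every published aggregate is reached — 156
concepts (86 document-expected, 12 qualifier values, 58 groups) and a
terms-per-concept distribution of 24/29/7/8/6/5/0/3/4 concepts carrying
1–8/>8 terms, with lack-of-energy keeping the maximum of 12. One published
aggregate cannot be honored: the stated total of 246 terms is arithmetically
incompatible with that distribution, whose minimum is 258 (219 terms from the
1–8 bins plus at least 12+9+9+9 from the four >8 concepts). The
reconstruction follows the distribution and therefore holds 258 terms; the
acceptance suite records the published 246 and fails by that fixed margin,
on purpose.

Because the padding is synthetic, tests against the full fixture demonstrate
only that the *counting machinery* matches the published aggregates — they say
nothing about the unpublished concepts themselves.

## Extraction

Extraction is deliberately rule-based and deterministic (no statistical NER,
no learned negation):

1. **Tokenization** over words that may contain internal hyphens, slashes and
   apostrophes ("bed-ridden", "w/c"), with sentence ids assigned at `.`, `;`
   and newline.
2. **Term matching**: greedy longest match, left to right, at word
   boundaries, never crossing a sentence break — "wheel chair" is one match,
   never a nested shorter one. Excluded ambiguous surfaces ("dressing",
   "supine", "working", "eating", "strength", "incontinence") never match,
   though longer surfaces containing them ("difficulty dressing") still do.
3. **Qualifier resolution**: the cue nearest to the match within the same
   sentence and a 5-token window (configurable in `cues.yaml`) is mapped onto
   the concept's axis; on an exact distance tie the preceding cue wins, since
   ability and negation cues typically precede in clinical English. Cues
   intrinsic to the matched surface ("unable to run") override context.
4. **Assertion**: negated iff a negation cue (no / denies / without / not /
   never) precedes the match within the window.

Three design points deserve explanation:

* **Cue lexicons are a package decision.** The ontology names the qualifier
  *values* but not the textual cues that signal them; the shipped YAML maps,
  e.g., can/independent(ly)/unassisted to *able* and
  difficulty/assist(ed)/needs help to *with difficulty*. Edit the file to
  retarget a corpus.
* **Negation vs. the absent qualifier.** For ability and status concepts,
  negation flips the assertion only. For frequency-axis concepts a denial
  ("denies fatigue") produces a finding that is *negated* and
  *absent*-qualified: the denial is itself scoreable evidence of absence,
  which several instrument rules reward. Scoring therefore accepts findings
  that are asserted, or negated with the absent qualifier; frailty
  aggregation uses asserted findings only.
* **Concept axis inference.** Ability concepts are recognized by name
  ("able …"/"ability …"); concepts whose score table carries real Rockwood
  ratings on off-axis levels (bed-ridden, wheelchair-bound, paralysis) are
  single-level status findings; everything else takes frequency qualifiers.

## Instrument scoring

Katz, Barthel and SF-36 are computed by one generic rule engine over TSV rule
tables. A rule row is an antecedent (one or two concept/scope/qualifier
clauses, optionally course-constrained) and a point value for its question
block; rows of a block with equal points are OR-alternatives, two clauses in
a row are a conjunction. Two engine-level conventions:

* **Worst satisfied row wins.** A block's value is the minimum points over
  its satisfied rows. This resolves conflicting evidence (able and unable
  findings for one concept) to the clinically conservative reading without
  needing per-concept polarity, and makes duplicate findings idempotent.
* **Missing evidence is uncovered, not zero.** Katz/Barthel items without
  evidence contribute 0 and lower the reported coverage; SF-36 sections
  average only covered blocks and return `NA` ("no evidence") when none is
  covered, because the published averaging rules presuppose evidence.

Instrument-specific notes:

* **Katz** counts able-qualified bathing/dressing/toileting/feeding, an able
  transfer, and both-kind continence (unqualified continence or
  absent-qualified incontinence per kind): 0–6.
* **Barthel**'s printed rule contributions sum to 19 under the
  "both kinds of continence = 2 total" reading and 21 under "2 per kind" —
  neither reaches the published 0–20 scale exactly. The scorer reports the
  raw rule sum with the published bounds as metadata, never rescaling;
  `continence_per_kind = TRUE` switches readings. An unable-qualified
  transfer scores 0 like an absent one, consistent with the Katz rule and
  the worst-wins convention.
* **SF-36** multi-question blocks ("covers 3 questions") are single blocks
  whose weight in the section average equals their question count, matching
  the printed per-block totals (300 across three questions). The parent-level
  rules for personal care (question 12) and community living (question 32)
  match the named concept only (`scope = self`), keeping them independent of
  the child-level Barthel rules. Question numbering follows the published
  rule table verbatim even where it differs from other SF-36 layouts.

## Instrument interpretation

Ten instruments' published category thresholds ship as data
(`instrument_criteria.tsv`), normalized to closed integer intervals exactly
as printed. Unlabelled complements needed for exhaustiveness (Tinetti 25–28,
FAQ 0–4) are marked as derived in the notes column. Two rows are stored
verbatim but flagged `caution` and excluded from the exhaustive-mapping
property: the ADL screen ("18 independent / 6 very independent" is internally
inconsistent as printed) and the direction-only Lawton IADL total. A bare
"IADL" mention is read as the Lawton 0–8 total — which scale a bare mention
refers to is genuinely undecidable, and the 0–8 total is the documented-score
reading; per-item 0/1/2 values are reachable via "IADL item". Morse, FAQ and
Braden bounds not printed with the criteria use the standard published maxima
(125, 30) and minimum (6).

The Rockwood crosswalk is a banding convention of this package: the
least-frail category of an instrument maps into Rockwood 1–3, intermediate
categories into 4–6, the most-frail into 7–9; no exact within-band placement
is claimed.

## Frailty profiles

`aggregate_profile()` maps each asserted, scored finding to one of seven
aggregation groups by subtree descent (professional services, physical
examination, activity/exercise, mobility, daily living, eating/drinking,
social history — the current subtrees corresponding to the seven draft-era
groups) and reports the per-group maximum Rockwood score. Pairings without a
published rating (e.g. unable-mobilize) are excluded from maxima rather than
interpolated. The profile is exactly the feature a downstream outcome model
would consume; no such model is included.

## Synthetic notes

`generate_note()` renders planned findings as template sentences — a lexicon
term plus cue words drawn from the extractor's own cue lexicon — and records
gold annotations by construction, not by running the extractor. Rendering
cues are chosen so that no cue+term concatenation accidentally forms a longer
lexicon surface, which is what makes exact recovery
(recall = precision = 1.0) a meaningful property of the extractor rather
than a tautology. A single integer seed drives all sampling; corpus seeds
derive per-note seeds, so corpora are reproducible as wholes.

The generator emulates short snippet-like narratives: one finding per
sentence, optional distractor sentences built around excluded ambiguous
terms, negation and distractor probabilities as dials. It does **not**
emulate real note structure — section headers, abbreviations outside the
lexicon, misspellings, coordinated clauses, or cue phrasings outside the cue
lexicon. Passing the closed-loop tests therefore shows the pipeline is
internally consistent and the rules are implemented faithfully; it does not
certify recall on real clinical text.

## Problem sizes and numerical choices

The test suite exercises: exhaustive Katz enumeration (3^5 slot states × 4
continence states ≈ 1 000 engine calls against an independent oracle), a
200-note closed-loop corpus at a fixed seed, 40 randomized monotonicity
probes across the three instruments, enumeration of every in-bounds integer
score for the interpretation criteria, and 25 randomized aggregation draws
of up to six findings against a brute-force oracle. These sizes were chosen
to cover the rule space within seconds of compute. Rockwood values are
compared exactly (they are table lookups); SF-36 comparisons use a 1e-9
slack for floating-point division only.

## Known limitations

* The extractor's qualifier adjudication (nearest cue, preceding wins on
  ties) is a package decision; the source material does not state how its
  NLP systems adjudicated conflicting cues in one sentence.
* Term lists outside the individually documented concepts are fixture
  choices, and the full-fixture padding is synthetic (see above).
* Per-concept will-fix/relevance ratings exist only for the handful of
  individually published concepts; fleet-wide statements ("52 concepts rated
  highly relevant by all raters") cannot be reconstructed per concept.
* No XLSX reader is bundled; supplement sheets must be converted to TSV.
* Out of scope by design: statistical snippet classifiers, mortality
  prediction models, STS score computation, SNOMED-CT release ingestion and
  description-logic reasoning (SCTIDs are annotations only).
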