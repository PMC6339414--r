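# ccfo — Cardiac-Centered Frailty Ontology toolkit

Frailty — diminished physiological reserve across mobility, self-care,
energy, mood and cognition — drives decisions between major cardiac surgery,
transcatheter intervention, and medical management, yet it is mostly recorded
as free-text narrative rather than structured instrument scores. `ccfo` is an
executable toolkit around the Cardiac-centered Frailty Ontology (CCFO), a
SNOMED-CT-compatible ontology of frailty *findings* (the clinician's recorded
conclusions, in the OGMS sense). It is intended for clinical-NLP researchers
and informaticists who need to extract frailty evidence from notes and turn
it into instrument scores and patient-level frailty features.

The package provides:

- **Ontology model** — concepts (CCFOID, optional SCTID, role), an
  indicator-term lexicon (terms suggest an author was thinking of a concept;
  they are not synonyms), the 12 qualifier values
  (able / with difficulty / unable; high / mid frequency; absent;
  chronic / short-duration / sudden-onset course), per concept-level Rockwood
  scores with will-fix and cardiac-relevance ratings, and an
  excluded-ambiguous-term list. Fixtures are plain TSV; OWL (RDF/XML) is an
  import/export dialect. `validate_ontology()` reports integrity violations
  as data.
- **Finding extraction** — lexicon matching (greedy longest match at word
  boundaries), qualifier and course resolution from configurable cue
  lexicons, and assertion (asserted/negated) detection with a sentence-local
  token window.
- **Instrument scoring** — rule-based Katz ADL (0–6), Barthel index and
  SF-36 section scores computed from finding sets; rule tables ship as TSV.
- **Instrument interpretation** — published category thresholds for ten
  frailty instruments (Katz, Barthel 0–100, FIM, Morse/MRT, Tinetti, Braden,
  FAQ, IADL variants, ADL screen) plus a crosswalk onto Rockwood bands
  (1–3 / 4–6 / 7–9).
- **Frailty profiles** — group-wise maximum Rockwood aggregation of findings
  into a per-patient feature row.
- **Synthetic notes** — a seeded generator of clinical-note-like snippets
  with gold-standard finding annotations, so the whole pipeline is testable
  without clinical data.

## Worked example

```r
library(ccfo)
ont <- ccfo_core_ontology()

note <- "Pt is wheelchair bound. Denies fatigue; unable to dress himself. Braden scale: 14"
(fnd <- extract_findings(ont, note))
#>   concept_id  qualifier course assertion start end         surface
#> 1    1121223 only-level   <NA>  asserted     6  16      wheelchair
#> 2     132222     absent   <NA>   negated    31  38         fatigue
#> 3     112442     unable   <NA>  asserted    40  55 unable to dress

aggregate_profile(fnd, ont)
#> <frailty profile> per-group maximum Rockwood score:
#>   seen by professional allied to medicine  no evidence (n=0)
#>   physical examination finding             no evidence (n=0)
#>   activity exercise pattern                no evidence (n=0)
#>   ability to move                          6 (n=1)
#>   activity of daily living                 7 (n=1)
#>   eating feeding drinking ability          no evidence (n=0)
#>   social and personal history finding      no evidence (n=0)
#>   overall: 7

score_barthel(fnd, ont)
#> <barthel> total 1 on scale [0, 20]
#>   item coverage 0.22

interpret_score("Braden", parse_instrument_mention(note)$raw)
#> <braden 14> moderate risk (intermediate)
```

Reading the output: the wheelchair-bound finding carries Rockwood 6 and the
unable-dressing pairing 7, so the mobility and daily-living groups report
those maxima and the overall frailty feature is 7 (severely frail region of
the 9-point scale). Barthel credits 1 point (wheelchair mobility rung) over
the two rule items with evidence; denied fatigue is recorded as
absence-of-deficit evidence, not a deficit. The Braden 14 maps to the
published "moderate risk" pressure-ulcer band.

A fully synthetic end-to-end run:

```r
corp <- generate_corpus(10, ont, seed = 42, profile = "independent")
fnd <- extract_findings(ont, corp$notes[[1]]$text)
score_katz(fnd, ont)$total
#> [1] 6
```

## Layout

```
inst/extdata/    concepts.tsv terms.tsv scores.tsv   core ontology fixture
                 excluded_terms.txt groups.tsv       exclusions, aggregation groups
                 cues.yaml                           extraction cue config
                 katz_rules.tsv barthel_rules.tsv sf36_rules.tsv
                 instrument_criteria.tsv             interpretation thresholds
exec/ccfo        thin CLI (extract | interpret | simulate | profile)
vignettes/       methods notes: model, rules, design decisions, limitations
```
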