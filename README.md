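# perisharm

Rule-based detection of perinatal self-harm mentions in free-text
psychiatric clinical notes, with service-user-level case finding and a
full diagnostic-statistics evaluation battery.

## The problem

Acts of self-harm during pregnancy and the postnatal year are clinically
important but poorly captured by structured fields in electronic health
records: they live in free text, surrounded by negations ("denies any
self-harm"), ideation ("thoughts of cutting herself"), third-party events
("her mother took an overdose"), historical references ("took an overdose
ten years ago") and treacherous shorthand ("OD" is both an overdose and a
once-daily dosing instruction). `perisharm` is for clinical-NLP
researchers and mental-health epidemiologists who need to find
service-users with documented acts of self-harm in a note corpus, audit
every decision the system made, and quantify its validity.

## The method

The pipeline applies five layers in sequence:

1. **Linguistic preprocessing** — sentence detection, tokenisation with a
   clinical exception list (`self-harm`, `fh/o`, … stay single tokens),
   part-of-speech tagging, lemmatisation and a shallow dependency parse,
   all rule-based and deterministic.
2. **Lexical tagging** — 13 semantic lexicons (self-harm terms, harm
   actions, body parts, family members, hedging, intent, medication,
   modality, negation, reported speech, life stages, past and present
   references) tag tokens by lemma or surface.
3. **Mention detection** — declarative token-sequence rules build mention
   spans (indicative noun; adjective + noun; verb + object; hazard verb +
   complement) and exclusion rules cancel traps ("Sertraline 50mg OD AM",
   "jump to conclusions"); header rules mark history sections.
4. **Negation detection** — a mention is negative iff it heads a `neg`
   dependency, its governor is a negated reported-speech verb, it is
   governed by a negation word, or it is followed by a symbol negation
   ("Suicide attempts: X").
5. **Contextual search** — a ±10-token window assigns status
   (hedging/modality/family cues → non-relevant) and temporality
   (past/life-stage cues or history sections → historical; default
   current).

A **true mention** is `status = relevant ∧ polarity = positive ∧
temporality = current`. Users are flagged when they have ≥ k true
mentions pooled over all their notes (k = 2 by default: real events are
re-documented at later visits, so a single unrepeated mention is weak
evidence).

Evaluation uses span matching (exact or overlap), micro/macro
precision/recall/F per attribute, Cohen's κ, and — at user level —
likelihood ratios LR⁺ = sens/(1−spec), LR⁻ = (1−sens)/spec with
log-transform confidence intervals, and post-test probabilities via the
odds transform.

## Worked example

```r
library(perisharm)
doc <- annotate_note(paste(
  "Past psychiatric history: two overdoses.",
  "Progress: she was reviewed at home today and denies any self-harm.",
  "2 x OD this week."))
mention_table(doc)[, c("text", "status", "temporality", "polarity")]
#>        text   status temporality polarity
#> 1 overdoses relevant  historical positive
#> 2 self-harm relevant     current negative
#> 3        OD relevant     current positive
```

The overdoses sit inside the history section (which runs from its header
to the next recognised header); the denied mention is negated via the
dependency rule; only the shorthand "2 x OD" is a true (relevant,
current, positive) mention. Aggregating:

```r
aggregate_users(mention_table(doc))
#>   user_id n_documents n_mentions_total n_true_mentions flagged_plain flagged_heuristic
#> 1       u           1                3               1          TRUE             FALSE
```

One true mention flags the user plainly but not under the ≥2 heuristic.

User-level validity statistics from a 2×2 confusion matrix:

```r
cm <- reconstruct_confusion(n_total = 152, n_gold_pos = 29, n_flagged = 29,
                            precision_min = 0.69, recall_min = 0.69)
lr <- likelihood_ratios(cm)
round(lr$lr_pos, 1)                                      # 9.4
round(100 * post_test_probability(29/152, lr$lr_pos), 1) # 69
```

A flagged user's probability of being a genuine case rises from the 19%
base rate to 69%.

A command-line interface wraps the same functions
(`inst/cli/perisharm`): `annotate`, `aggregate`, `evaluate`, `simulate`
and `run-all`.

## Scope

The package ships reconstructed lexicons and rules seeded from published
example material; they are deliberately small, auditable and extendable
via plain-text configuration. It does not de-identify text, normalise
dates, or connect to any EHR system, and the synthetic corpus generator
imitates the *constructions* of psychiatric progress notes, not their
full linguistic variety — see the methods vignette
(`vignettes/perinatal-selfharm-pipeline.Rmd`) for what that does and does
not establish.
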