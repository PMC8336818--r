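---
title: "Detecting perinatal self-harm in clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting perinatal self-harm in clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisharm)
```

## The task and its assumptions

Free-text psychiatric notes document acts of self-harm amid negations,
ideation, risk language, family history and shorthand. The pipeline's
job is to find *mentions* of self-harm acts and classify each on three
independent axes:

* **status** — did an act occur (`relevant`) or is this
  thought/plan/risk/third-party/conditional material (`non-relevant`)?
  The data model also admits `uncertain`, which exists in manually
  annotated reference standards, but no shipped rule emits it: rules are
  meant to commit, and uncertainty is an annotation-workflow concept.
* **temporality** — `current` (roughly within a month of the note) or
  `historical`. Because the corpus selection upstream is assumed to
  restrict notes to the perinatal window, cue words rather than calendar
  arithmetic decide this; that is a stated limitation, not an oversight
  (dates in clinical prose are too irregular for a rule-based tool to
  anchor reliably).
* **polarity** — asserted (`positive`) or denied (`negative`).

A mention with no cues at all is `(relevant, current, positive)`: the
default bias is towards treating a bare self-harm keyword as a real,
recent, asserted event, which matches how clinicians write ("2 x OD").

A **true mention** is relevant ∧ current ∧ positive, and a service-user
is flagged when ≥ k true mentions occur across all their notes (k = 2 by
default). The heuristic's rationale is behavioural, not statistical: a
real self-harm event is followed up at later visits, so it generates
repeat documentation, while a single unrepeated mention is often noise.
For the same reason repeat mentions of one event are deliberately *not*
deduplicated. Whether the k mentions must come from distinct documents
is configurable (`distinct_documents`, default off).

## Layer 1: linguistic preprocessing

The preprocessor is a deterministic rule-based parser written for the
telegraphic register of progress notes: a regex tokeniser whose
exception list keeps clinical multi-part terms (`self-harm`, `fh/o`,
`d/s/h`, …) as single tokens, closed-class word lists plus suffix
heuristics for coarse part-of-speech tags, a small lemmatiser (irregular
table plus `-s/-es/-ies/-ing/-ed` stripping with e-restoration), and a
shallow dependency pass producing the relations the later layers consume
(`nsubj`, `dobj`, `neg`, `aux`, `prep`/`pobj`, `xcomp`, `det`, `amod`,
`compound`). The dependency pass builds verbal groups, chunks noun
phrases, attaches subjects and objects by position, and guarantees a
tree per sentence (cycles are reattached to the root).

This is not a general statistical parser and does not try to be one; it
is scoped to the constructions the attribute rules need, and the
canonical parses (e.g. *she did not cut herself* with `not --neg-->
cut`) are frozen as regression tests. The exception list and all
lexicons are plain text, so failures on new shorthand are fixed by
configuration, not code.

Character offsets are 0-based and half-open everywhere, including all
standoff I/O. Within R, token rows are 1-based (`token_id`), which is
the idiomatic compromise.

## Layer 2: lexical tagging

Thirteen lexicons (SH, BODY_PART, HARM_ACTION, FAMILY, HEDGING, INTENT,
MED, MODALITY, NEGATION, R_SPEECH, LIFE_STAGE, PAST, PRESENT) tag
tokens by lemma first, surface as fallback, case-insensitively — so
*Denies* matches the entry *deny*. Multi-word terms ("suicide attempt")
match as token sequences; the longest match wins and equal-length
matches from different categories coexist. Tagging replaces previous
tags, hence is idempotent.

The shipped lexicons are a deliberately small reconstruction seeded from
published example terms plus obvious clinical inflections, and every
hyphenated lexicon term is mirrored in the tokenisation exception list
(a consistency the tests enforce). `OD` sits in the SH lexicon even
though it is ambiguous with "once daily"; the grammar layer, which can
see context, owns that disambiguation.

## Layer 3: mention grammar

Mention rules are declarative (`name priority action : pattern`) and
live in a plain-text file so a clinician can audit them. Span policy
follows the coding rules for what the annotation should cover:

* a direct keyword alone — *overdose*, *DSH*, *suicide attempts*;
* an indicative noun alone — *scratches* in "she had scratches on her
  arm" (not the sentence);
* keyword adjective + modified noun — *self-harming impulse*;
* keyword verb + its object — *cut herself*, *cut her left wrist*;
* hazard verb + complement — *fell off*, *jump through a window*.

Overlapping matches resolve by longest span, then rule priority, then
leftmost position; longest-match is the standard convention where the
source material is silent. Matched spans extend to cover any semantic
tag they partially overlap, so multi-word lexicon terms are annotated
whole.

Exclusion rules *remove* mentions rather than preventing them, keeping
the pipeline auditable: the dosage reading of `OD` requires a dose unit
(e.g. `50mg`) or a frequency marker (`AM`, `BD`, `nocte`, …) within two
tokens — a bare drug name is not enough, because "took an OD of
paracetamol" is a genuine overdose; and idiomatic `jump` complements
("to conclusions", "down the stairs") are excluded while genuine ones
("through a window", "to kill herself") survive. An exclusion never
outranks an inclusion rule of higher priority.

Third-party mentions ("her mother took an overdose") are detected and
then demoted to non-relevant by layer 5 rather than suppressed here, so
they stay countable for audit. `suicide` generates mentions ("no
history of suicide" → negative polarity), because missing those is the
most damaging span error a keyword tool can make in this domain.

History sections open at a recognised history header ("Past psychiatric
history:", "Forensic history:", …) and close at the next recognised
header of either kind or the end of the document; headers are recognised
at sentence starts and immediately after a previous header's colon,
since notes chain headers on one line.

## Layers 4–5: attributes

**Polarity** is dependency-based. A mention is negative when (a) one of
its tokens governs a `neg` dependency ("she did *not* cut herself");
(b) its governor is a reported-speech verb that is itself negated ("she
did not *report* harming herself"); (c) a word in its governing chain is
NEGATION-tagged or governs a `neg` dependency ("she *denies* any
self-harm", "*no* history of suicide"); or (d) it is followed on its
line by a colon and a negation symbol ("Suicide attempts: X", with
symbols `X`, `✗`, `nil`, `0`, `none`, `no`).

**Status and temporality** use a context window of `window_width`
tokens (default 10) each side of the mention, excluding the mention
itself. The window is a pure token window by default — it crosses
sentence boundaries, because that is what a token-window definition
means; a sentence-bounded variant is kept behind
`sentence_bounded_window` for ablation. HEDGING or MODALITY in the
window demotes status to non-relevant; a FAMILY token demotes it when it
is within three tokens to the left or is the subject of the mention's
clause (plain window co-occurrence is too coarse — "patient overdosed;
her mother was informed" must stay relevant). HEDGING cues are ignored
when the cue word is a verb: "she *thought* the self-harm would kill
her" is reported cognition about a real event, not ideation.

Trailing modals are the one place the package deliberately deviates from
a strict reading of the windowed search: a MODALITY cue *after* the
mention demotes it only when the modal's syntactic scope covers the
mention (not when the mention is merely the subject of a separate
modalised clause). The strict behaviour — any trailing modal demotes —
is retained behind `paper_faithful_mode` so both can be compared; the
fixed behaviour is the default because the strict one is a documented
error mode.

Temporality: PAST or LIFE_STAGE in the window → historical, except that
"chronic/ongoing history of X" is coded current (a chronic reference
asserts a potentially ongoing problem). When both PAST and PRESENT cues
occur, the cue nearest to the mention wins and ties fall to current,
which preserves the stated default in the absence of clear historical
marking; this also resolves coordinations like "no current or past
suicide attempts" to historical-and-negative, since *past* sits closer
to the span than *current* and the shared determiner *no* negates the
phrase head. Mentions inside a history section are historical regardless
of window cues. The PRESENT lexicon thus acts as a tie-breaker rather
than an override — the least committal reading consistent with a
current-by-default policy.

All three attributes read only layer 1–3 output, so their resolution
order is immaterial, and adding a PAST cue can only move a mention
current → historical, never back (a property the tests exercise).

## Evaluation machinery

Span matching offers `exact` (identical character spans) and `overlap`
(≥ 1 shared character, greedy left-to-right with longest-overlap
tie-break) modes; exact is the default because it is the stricter
surface. Attribute metrics are computed over matched pairs only, so
unmatched spans affect span metrics but not attribute metrics — which is
why, for single-label attributes, micro precision, recall and F collapse
to accuracy and print identical values. Zero-denominator conventions:
empty gold and empty predictions score 1 (nothing to find, nothing
found); no predicted positives yields an undefined precision reported
as `NA`; a defined precision/recall pair of 0 gives F = 0.

User-level validity uses the 2×2 machinery: per-class (minority =
self-harm cases) precision/recall/F, macro averages, Cohen's κ,
likelihood ratios and post-test probabilities.
`reconstruct_confusion()` inverts published per-class statistics
(cohort size, gold positives, flagged count, minority precision and
recall at printed 2-dp precision) back to integer counts, refusing
inputs whose implied true-positive counts disagree: with 152 users, 29
gold-positive, 29 flagged and precision = recall = 0.69 it returns
tp = 20, fp = 9, fn = 9, tn = 114, from which LR⁺ = 9.4, LR⁻ = 0.33,
post-test probabilities 69.0% and 7.3%, macro-F 0.81 and κ 0.62 all
follow by computation. Confidence intervals for likelihood ratios use
the log-transform normal approximation
exp(ln LR ± z·SE), SE(ln LR⁺) = √(1/tp − 1/(tp+fn) + 1/fp − 1/(fp+tn)),
the standard diagnostic-test method; no other method is attempted, and a
zero-false-positive matrix reports LR⁺ = ∞ with a `perfect_prediction`
flag rather than a number. Inter-annotator agreement between more than
two raters micro-averages the pooled pairwise counts.

## The synthetic corpus generator

`generate_corpus()` assembles short pseudo-notes from neutral filler
sentences and phenomenon templates (plain acts, negations, hedged
ideation, historical references, third-party events, shorthand, and
exclusion traps), emitting gold spans and attributes by construction and
recomputing per-user gold flags from those mentions. Defaults
(`fixture_spec()`): 50 users, 1–6 notes each, a 25% chance a user is a
self-harm case, and a 30% chance per note that a case documents a true
mention — which yields roughly one flagged user in five and gives most
affected users more than one true mention, the shape that motivates the
k = 2 heuristic. Phenomenon sentences are separated by two fillers so
one sentence's cue words stay outside its neighbours' ten-token windows;
without that spacing the generator's per-sentence gold would be wrong
*about its own corpus* under a cross-sentence window, which is a fact
about windows, not about the pipeline.

What passing on this corpus shows: the five layers implement the
documented constructions, exclusions and cue semantics, end to end and
deterministically. What it cannot show: performance on real EHR text,
whose spelling variation, layout artefacts, copy-paste duplication and
unbounded lexical creativity the templates do not model. The worked
example bank — every construction the rules are specified against, with
its expected annotation — is the regression surface that keeps the rule
set honest; the synthetic corpus tests composition and aggregation at
scale. Problem sizes in the shipped tests (50 users, ~170 notes, 1000
random label sets for the metric oracles, 10 000 draws for the
chance-level κ check) were chosen as the smallest that exercise every
code path with stable statistics.

## Numerical and degenerate-input choices

* Empty text is a valid document with zero tokens and zero mentions.
* κ returns 1 for identical vectors even when only one class is
  realised (expected agreement 1 is treated as agreement, not as 0/0),
  and 0 when expected agreement is 1 but observed is not.
* `token_window(width = 0)` is empty; spans out of bounds are
  programming errors, not data conditions.
* Rule files are validated on load (duplicate names, malformed
  patterns, unknown keys fail fast with the offending text).
* A missing lexicon category names the absent category in its error.
* Corpus/standoff readers fail with the missing column named; the CLI
  converts these to non-zero exits.

## Known limitations

* Temporality rests on cue words; relative dates ("two weeks before
  delivery") and bare date stamps are not resolved.
* The shallow parser mis-handles long coordinated or subordinate
  sentences; the negation rules then fall back towards the default
  positive polarity rather than guessing.
* Lexicons are seed reconstructions; recall on real corpora depends on
  extending them (the S1-style full keyword lists are configuration,
  not code).
* `risk to self` headers are treated as prospective risk-assessment
  content (non-relevant); occasionally clinicians use them for past
  events, and that reading is only recoverable by configuration.
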