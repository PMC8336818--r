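# Multi-part clinical terms kept as single tokens by the tokeniser.
# One term per line; matched case-insensitively when delimited by
# whitespace or punctuation.  Every hyphenated or slashed lexicon term
# must be listed here so lexical tagging sees it as one token.
self-harm
self-harms
self-harming
self-harmed
self-injury
self-injuries
self-injurious
self-inflicted
self-poisoning
self-mutilation
self-cutting
self-strangulation
fh/o
d/s/h
h/o
p/w
o/e
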