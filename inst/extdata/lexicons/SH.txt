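# Self-harm keywords (reconstructed seed list; extend via config).
# Hyphenated / slashed entries must also appear in token_exceptions.txt.
DSH
d/s/h
self-harm
self-injury
self-harming
self-injurious
self-inflicted
self-poisoning
self-mutilation
self-cutting
self-strangulation
overdose
overdoses
OD
suicide
suicide attempt
suicide attempts
attempted suicide
parasuicide
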