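cut
burn
hit
lacerate
scratch
stab
slash
strangle
hang
poison
jump
fall
ingest
swallow
harm
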