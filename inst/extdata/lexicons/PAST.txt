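previous
previously
past
historical
historically
history
hx
ago
former
formerly
earlier
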