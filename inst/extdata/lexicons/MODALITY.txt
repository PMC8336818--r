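could
would
can
may
might
must
should
possible
possibly
possibility
potential
potentially
perhaps
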