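mother
father
daughter
son
sister
brother
husband
wife
partner
mum
dad
grandmother
grandfather
aunt
uncle
cousin
friend
flatmate
neighbour
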