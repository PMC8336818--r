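olanzapine
paracetamol
aspirin
sertraline
fluoxetine
citalopram
diazepam
quetiapine
risperidone
lithium
ibuprofen
zopiclone
promethazine
lamotrigine
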