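# Section headers recognised in clinical notes.  A history section opens
# at a [history] header and closes at the next header of either kind or
# at the end of the document.  Headers match at the start of a line or
# sentence and are followed by a colon.
[history]
past psychiatric history
past medical history
past history
previous psychiatric history
previous history
forensic history
personal history
family history
history

[other]
current presentation
presenting complaint
history of presenting complaint
mental state examination
mental state
impression
diagnosis
plan
medication
medications
risk assessment
risk to self
risk to others
social circumstances
progress
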