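# "current" means within roughly one month of the note.
Monday
Tuesday
Wednesday
Thursday
Friday
Saturday
Sunday
current
currently
recent
recently
today
tonight
yesterday
now
presently
ongoing
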