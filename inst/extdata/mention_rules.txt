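# Token-sequence grammar for self-harm mention spans (reconstructed rule set).
#
# One rule per line:   name  priority  action : pattern
#   action  = mention | exclude
#   pattern = whitespace-separated elements, each a set of alternatives
#             separated by "|"; an alternative is one or more conditions
#             joined by "&"; a condition is key=value[,value...].
#   keys    = surface, lemma, pos, sem, re (regex on the surface form)
#   element quantifiers: trailing "?" (optional) or "*" (0-3 tokens, greedy
#             with backtracking).
# Matching is case-insensitive.  Overlapping matches are resolved by
# longest span, then highest priority, then leftmost.  A mention span is
# extended to cover any semantic tag it partially overlaps, so multi-word
# lexicon terms (e.g. "suicide attempt") are annotated whole.
#
# exclude rules remove previously created mentions overlapping their match,
# unless the mention came from an inclusion rule of higher priority.

# --- span construction -------------------------------------------------
# keyword verb + the object it relates to ("cut herself", "cut her wrist")
sh_verb_object   90 mention : sem=SH,HARM_ACTION&pos=VERB pos=DET,NUM,ADJ* sem=BODY_PART,SH|pos=PRON
# hazard verb + infinitive purpose ("jump to kill herself")
sh_hazard_inf    86 mention : lemma=jump&pos=VERB surface=to lemma=kill,die,end,harm pos=PRON?
# hazard verb + particle/preposition complement ("fell off", "jump through a window")
sh_hazard_comp   85 mention : lemma=jump,fall&pos=VERB pos=ADP,PART pos=DET? pos=NOUN,PRON?
# keyword adjective + the noun it modifies ("self-harming impulse")
sh_adj_noun      80 mention : sem=SH&pos=ADJ pos=NOUN
# indicative noun alone ("scratches")
sh_harm_noun     60 mention : sem=HARM_ACTION&pos=NOUN
# direct self-harm keyword ("overdose", "DSH", "suicide attempt")
sh_keyword       50 mention : sem=SH

# --- exclusions (error-analysis traps) ---------------------------------
# "OD" as a dosage frequency, not an overdose: dose unit or frequency
# marker adjacent ("Sertraline 50mg OD AM", "Olanzapine 10mg OD nocte")
excl_od_dose    100 exclude : re=^[0-9]+(\.[0-9]+)?(mg|mcg|g|ml)$ surface=OD
excl_od_freq    100 exclude : surface=OD surface=AM,PM,BD,TDS,QDS,OM,ON,nocte,mane,daily
# idiomatic / non-self-harm "jump" complements
excl_jump_idiom 100 exclude : lemma=jump surface=to,down pos=DET? lemma=conclusion,stair
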