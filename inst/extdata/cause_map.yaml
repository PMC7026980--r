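# Editable cause-of-death grouping: cause label -> ICD-10 range strings.
# Ranges are inclusive on three-character category roots; "A-R" spans
# A00-R99. The cancer block is bounded at D48 (end of the neoplasms
# chapter).
Non-accidental: A-R
Accidental: V-Y
All CVD: I00-I99
IHD: I20-I25
CBV: I60-I69
CHF: I50
All respiratory: J00-J99
COPD: J40-J44
Pneumonia: J12-J18
All cancer: C00-D48
Lung cancer: C34
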