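# Default currency-metabolite stoplist (editable).
# One id per line; matching against network node ids is case-insensitive.
h2o
co2
atp
adp
pi
nadh
nad
nadph
nadp
h
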