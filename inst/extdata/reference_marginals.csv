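variable,state,probability
lden,low,0.310
lden,moderate,0.385
lden,high,0.305
sensitivity,low,0.350
sensitivity,moderate,0.327
sensitivity,high,0.323
annoyance,low,0.346
annoyance,moderate,0.313
annoyance,high,0.341
comfort,low,0.350
comfort,moderate,0.371
comfort,high,0.279
itl,low,0.326
itl,moderate,0.470
itl,high,0.204
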