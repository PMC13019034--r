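scenario,variable,state,probability
lden_high,lden,low,0
lden_high,lden,moderate,0
lden_high,lden,high,1
lden_high,sensitivity,low,0.350
lden_high,sensitivity,moderate,0.327
lden_high,sensitivity,high,0.323
lden_high,annoyance,low,0.252
lden_high,annoyance,moderate,0.284
lden_high,annoyance,high,0.464
lden_high,comfort,low,0.414
lden_high,comfort,moderate,0.358
lden_high,comfort,high,0.228
lden_high,itl,low,0.254
lden_high,itl,moderate,0.492
lden_high,itl,high,0.254
sensitivity_high,lden,low,0.310
sensitivity_high,lden,moderate,0.385
sensitivity_high,lden,high,0.305
sensitivity_high,sensitivity,low,0
sensitivity_high,sensitivity,moderate,0
sensitivity_high,sensitivity,high,1
sensitivity_high,annoyance,low,0.250
sensitivity_high,annoyance,moderate,0.320
sensitivity_high,annoyance,high,0.430
sensitivity_high,comfort,low,0.410
sensitivity_high,comfort,moderate,0.360
sensitivity_high,comfort,high,0.230
sensitivity_high,itl,low,0.254
sensitivity_high,itl,moderate,0.494
sensitivity_high,itl,high,0.252
lden_high_sensitivity_low,lden,low,0
lden_high_sensitivity_low,lden,moderate,0
lden_high_sensitivity_low,lden,high,1
lden_high_sensitivity_low,sensitivity,low,1
lden_high_sensitivity_low,sensitivity,moderate,0
lden_high_sensitivity_low,sensitivity,high,0
lden_high_sensitivity_low,annoyance,low,0.350
lden_high_sensitivity_low,annoyance,moderate,0.300
lden_high_sensitivity_low,annoyance,high,0.350
lden_high_sensitivity_low,comfort,low,0.350
lden_high_sensitivity_low,comfort,moderate,0.380
lden_high_sensitivity_low,comfort,high,0.270
lden_high_sensitivity_low,itl,low,0.320
lden_high_sensitivity_low,itl,moderate,0.460
lden_high_sensitivity_low,itl,high,0.220
lden_low_sensitivity_high,lden,low,1
lden_low_sensitivity_high,lden,moderate,0
lden_low_sensitivity_high,lden,high,0
lden_low_sensitivity_high,sensitivity,low,0
lden_low_sensitivity_high,sensitivity,moderate,0
lden_low_sensitivity_high,sensitivity,high,1
lden_low_sensitivity_high,annoyance,low,0.350
lden_low_sensitivity_high,annoyance,moderate,0.350
lden_low_sensitivity_high,annoyance,high,0.300
lden_low_sensitivity_high,comfort,low,0.350
lden_low_sensitivity_high,comfort,moderate,0.380
lden_low_sensitivity_high,comfort,high,0.270
lden_low_sensitivity_high,itl,low,0.325
lden_low_sensitivity_high,itl,moderate,0.455
lden_low_sensitivity_high,itl,high,0.220
lden_high_sensitivity_high,lden,low,0
lden_high_sensitivity_high,lden,moderate,0
lden_high_sensitivity_high,lden,high,1
lden_high_sensitivity_high,sensitivity,low,0
lden_high_sensitivity_high,sensitivity,moderate,0
lden_high_sensitivity_high,sensitivity,high,1
lden_high_sensitivity_high,annoyance,low,0.150
lden_high_sensitivity_high,annoyance,moderate,0.250
lden_high_sensitivity_high,annoyance,high,0.600
lden_high_sensitivity_high,comfort,low,0.481
lden_high_sensitivity_high,comfort,moderate,0.319
lden_high_sensitivity_high,comfort,high,0.200
lden_high_sensitivity_high,itl,low,0.180
lden_high_sensitivity_high,itl,moderate,0.510
lden_high_sensitivity_high,itl,high,0.310
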