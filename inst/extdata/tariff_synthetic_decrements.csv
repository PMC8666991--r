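# SYNTHETIC EQ-5D-5L value set (additive decrement form). This is NOT a
# published tariff: it is a stand-in with the qualitative structure of
# crosswalk-style value sets (anchor 1.0 at full health, a constant
# decrement for any problem, per-dimension level decrements, floor -0.59
# at state 55555, negative values = worse than dead). Replace with a
# licensed published value set for real analyses.
term,value
anchor,1.0
any_problem,0.060
MO2,0.040
MO3,0.050
MO4,0.200
MO5,0.330
SC2,0.040
SC3,0.060
SC4,0.210
SC5,0.280
UA2,0.030
UA3,0.050
UA4,0.160
UA5,0.220
PD2,0.050
PD3,0.070
PD4,0.250
PD5,0.360
AD2,0.050
AD3,0.070
AD4,0.240
AD5,0.340
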