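# units_T = C
# units_strength = N/m
# units_grammage = g/m2
# press_pressure_MPa = 3.5
# posthold_MPa = 0.1
# posthold_s = 6
# note = published reference tensile indices of handsheets (grammage 100 g/m2); strength back-computed as index * grammage
T_C,mc_pct,time_s,pressure_MPa,state,strength_Npm,grammage_gm2
NA,7,0,0,dry_test,2770,100
280,7,3,3.5,dry_test,4970,100
240,25,3,3.5,dry_test,6290,100
NA,7,0,0,wet_test,0,100
300,7,3,3.5,wet_test,2120,100
300,25,3,3.5,wet_test,2570,100
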