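marker,regime,S1-CF,S1-A,S2-F,turbidity,flow,median_nrmsep
FC,CSO,,x,x,,,0.88
EN-culture,CSO,x,,x,,,0.76
EC-culture,CSO,,x,x,,x,1.07
EC-qPCR,CSO,,x,x,,,1.17
EN-qPCR,CSO,,x,x,,,1.18
HB,CSO,,x,x,,,1.12
L3,CSO,,x,x,,,1.16
sHM,CSO,,x,x,,,1.16
FC,nonCSO,,x,x,,x,0.80
EN-culture,nonCSO,x,x,x,x,x,0.70
EC-culture,nonCSO,x,x,x,x,x,0.58
EC-qPCR,nonCSO,,x,x,x,x,0.71
EN-qPCR,nonCSO,x,,x,x,x,0.60
HB,nonCSO,,x,x,x,,0.56
L3,nonCSO,,x,x,,x,0.56
sHM,nonCSO,,x,x,,x,0.53
FC,combined,x,x,x,,x,0.73
EN-culture,combined,x,x,x,,x,0.67
EC-culture,combined,x,x,x,,x,0.61
EC-qPCR,combined,x,x,x,,x,0.67
EN-qPCR,combined,x,x,x,,x,0.66
HB,combined,x,x,x,,x,0.77
L3,combined,x,x,x,,x,0.74
sHM,combined,x,x,x,,x,0.73
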