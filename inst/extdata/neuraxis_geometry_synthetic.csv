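label,position_cm,major_radius_cm,minor_radius_cm,tissue_fraction
CM,0,2.40,0.65,0.62
C3,7,1.80,0.60,0.40
C5,12,1.60,0.55,0.42
C7,16,1.50,0.50,0.45
T2,20,1.30,0.35,0.45
T4,25,1.20,0.35,0.45
T5,28,1.15,0.34,0.45
T7,33,1.10,0.34,0.44
T9,38,1.10,0.36,0.42
T11,43,1.15,0.40,0.40
L1,50,1.60,0.50,0.35
L2,53,1.50,0.48,0.30
L5,60,1.30,0.42,0.20
S3,65,1.20,0.39,0.10
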