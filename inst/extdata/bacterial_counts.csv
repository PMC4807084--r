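treatment,compartment,mean,sem,letter,unit
Control,soil,1.98,0.06,b,1e7 cfu/g dry soil
UPMB10,soil,2.41,0.22,b,1e7 cfu/g dry soil
Br1,soil,5.85,1.61,a,1e7 cfu/g dry soil
Fr1,soil,2.36,0.18,b,1e7 cfu/g dry soil
S1r1,soil,4.22,0.96,ab,1e7 cfu/g dry soil
S3r2,soil,5.39,1.12,a,1e7 cfu/g dry soil
Control,rhizosphere,1.72,0.15,a,1e8 cfu/g root dry weight
UPMB10,rhizosphere,2.97,0.97,a,1e8 cfu/g root dry weight
Br1,rhizosphere,6.25,1.95,a,1e8 cfu/g root dry weight
Fr1,rhizosphere,4.84,1.16,a,1e8 cfu/g root dry weight
S1r1,rhizosphere,2.98,0.36,a,1e8 cfu/g root dry weight
S3r2,rhizosphere,3.79,1.08,a,1e8 cfu/g root dry weight
Control,endosphere,0.96,0.03,b,1e2 cfu/cm fresh root
UPMB10,endosphere,5.90,0.75,b,1e2 cfu/cm fresh root
Br1,endosphere,3.46,0.75,b,1e2 cfu/cm fresh root
Fr1,endosphere,10.90,0.72,b,1e2 cfu/cm fresh root
S1r1,endosphere,3.34,0.19,b,1e2 cfu/cm fresh root
S3r2,endosphere,726.77,89.39,a,1e2 cfu/cm fresh root
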