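strain,iaa_ug_ml,letter,n_replicates
UPMB10,10.10,b,3
Br1,4.91,c,3
Fr1,12.99,a,3
S1r1,10.55,b,3
S3r2,10.70,b,3
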