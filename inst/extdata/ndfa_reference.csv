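treatment,part,harvest_day,ndfa_pct,ndfa_sem,ndfa_letter_within,ndfa_letter_between,n_fixed_mg,n_fixed_sem,n_fixed_letter_within,n_fixed_letter_between,n_replicates
UPMB10,tassel,50,18.7,0.9,b,A,30.3,2.2,b,A,4
UPMB10,tassel,65,4.9,0.8,a,B,6.3,1.0,a,B,4
UPMB10,young_leaves,50,28.9,3.3,a,A,35.5,7.2,b,A,4
UPMB10,young_leaves,65,18.9,1.3,a,A,33.5,3.4,b,A,4
UPMB10,ear_leaves,50,23.3,1.5,c,B,31.0,2.7,b,B,4
UPMB10,ear_leaves,65,37.8,2.3,a,A,56.0,3.7,a,A,4
UPMB10,old_leaves,50,20.7,2.1,b,A,22.8,4.7,b,A,4
UPMB10,old_leaves,65,18.2,2.8,b,A,21.8,4.3,b,A,4
UPMB10,stalk,50,13.9,1.0,a,A,35.3,4.1,a,A,4
UPMB10,stalk,65,18.0,2.5,a,A,58.3,5.6,a,A,4
UPMB10,ear,65,16.5,1.2,c,,31.3,2.2,c,,4
UPMB10,plant_top,50,21.7,0.3,c,A,154.5,10.1,b,B,4
UPMB10,plant_top,65,19.9,0.5,b,B,206.8,4.3,b,A,4
Br1,tassel,50,11.4,2.0,c,A,15.8,2.8,c,A,4
Br1,tassel,65,3.3,1.2,a,B,4.0,1.7,a,B,4
Br1,young_leaves,50,19.1,2.0,b,A,22.8,3.4,bc,A,4
Br1,young_leaves,65,4.1,1.1,b,B,6.0,1.0,c,B,4
Br1,ear_leaves,50,18.8,4.7,c,A,27.0,5.9,b,A,4
Br1,ear_leaves,65,21.3,3.7,b,A,25.3,3.5,b,A,4
Br1,old_leaves,50,10.7,1.9,c,A,13.0,3.2,b,A,4
Br1,old_leaves,65,14.3,2.3,bc,A,16.8,2.5,bc,A,4
Br1,stalk,50,14.5,1.1,a,A,35.8,2.9,a,A,4
Br1,stalk,65,13.4,4.9,a,A,40.5,14.0,a,A,4
Br1,ear,65,6.7,0.8,d,,11.5,1.8,d,,4
Br1,plant_top,50,14.2,1.7,d,A,114.5,15.7,c,A,4
Br1,plant_top,65,10.6,0.8,c,A,103.8,9.5,c,A,4
Fr1,tassel,50,18.5,2.1,b,A,33.0,3.9,b,A,4
Fr1,tassel,65,7.2,1.9,a,B,8.8,2.2,a,B,4
Fr1,young_leaves,50,29.4,2.6,a,A,51.3,9.1,a,A,4
Fr1,young_leaves,65,19.9,1.8,a,A,43.8,3.9,ab,A,4
Fr1,ear_leaves,50,29.8,2.7,b,A,55.0,5.1,a,A,4
Fr1,ear_leaves,65,35.2,5.0,a,A,64.0,12.1,a,A,4
Fr1,old_leaves,50,32.4,2.5,a,A,56.5,6.7,a,A,4
Fr1,old_leaves,65,28.1,3.5,a,A,46.0,5.1,a,A,4
Fr1,stalk,50,17.4,2.5,a,A,49.5,7.5,a,A,4
Fr1,stalk,65,17.1,4.4,a,A,67.3,16.2,a,A,4
Fr1,ear,65,21.5,1.9,b,,46.0,6.2,b,,4
Fr1,plant_top,50,26.9,1.1,b,A,245.8,16.3,a,A,4
Fr1,plant_top,65,22.7,1.4,b,A,276.3,16.9,a,A,4
S1r1,tassel,50,24.4,1.2,a,A,45.5,3.8,a,A,4
S1r1,tassel,65,10.2,3.1,a,B,12.3,3.7,a,B,4
S1r1,young_leaves,50,32.2,1.4,a,A,57.0,5.6,a,A,4
S1r1,young_leaves,65,22.0,2.9,a,B,51.0,5.9,a,A,4
S1r1,ear_leaves,50,37.1,2.7,a,A,61.5,6.1,a,A,4
S1r1,ear_leaves,65,40.8,4.4,a,A,74.8,12.1,a,A,4
S1r1,old_leaves,50,34.1,2.2,a,A,50.8,6.8,a,A,4
S1r1,old_leaves,65,29.8,1.2,a,A,50.0,3.1,a,A,4
S1r1,stalk,50,17.0,3.8,a,A,47.8,11.0,a,A,4
S1r1,stalk,65,14.3,4.1,a,A,56.0,17.0,a,A,4
S1r1,ear,65,26.4,0.7,a,,58.8,2.9,a,,4
S1r1,plant_top,50,30.5,0.8,a,A,262.3,7.5,a,A,4
S1r1,plant_top,65,25.5,0.7,a,B,303.5,27.4,a,A,4
S3r2,tassel,50,10.0,2.0,c,A,17.5,3.8,c,A,4
S3r2,tassel,65,4.8,0.7,a,A,6.0,1.2,a,B,4
S3r2,young_leaves,50,10.0,2.8,c,A,16.8,6.2,c,A,4
S3r2,young_leaves,65,7.5,1.8,b,A,13.0,2.5,c,A,4
S3r2,ear_leaves,50,13.0,2.7,d,A,19.5,3.1,b,A,4
S3r2,ear_leaves,65,15.9,1.7,b,A,21.0,4.9,b,A,4
S3r2,old_leaves,50,14.0,4.0,bc,A,16.8,4.6,b,A,4
S3r2,old_leaves,65,8.3,2.1,c,A,10.0,2.1,c,A,4
S3r2,stalk,50,12.7,1.9,a,A,31.3,4.2,a,A,4
S3r2,stalk,65,12.8,3.4,a,A,41.3,9.8,a,A,4
S3r2,ear,65,6.3,0.9,d,,11.0,2.0,d,,4
S3r2,plant_top,50,12.0,1.6,d,A,101.5,8.5,c,A,4
S3r2,plant_top,65,8.7,0.7,c,B,101.5,6.7,c,A,4
inoculated_mean,tassel,50,16.6,1.5,,A,28.4,2.9,,A,20
inoculated_mean,tassel,65,6.1,1.1,,B,7.5,1.3,,B,20
inoculated_mean,young_leaves,50,23.9,1.8,,A,36.7,3.7,,A,20
inoculated_mean,young_leaves,65,14.5,2.2,,B,29.5,5.3,,B,20
inoculated_mean,ear_leaves,50,24.4,2.2,,B,38.8,3.8,,B,20
inoculated_mean,ear_leaves,65,30.2,3.1,,A,48.2,7.3,,A,20
inoculated_mean,old_leaves,50,22.4,2.1,,A,32.0,4.0,,A,20
inoculated_mean,old_leaves,65,19.7,2.6,,A,28.9,4.8,,A,20
inoculated_mean,stalk,50,15.1,0.9,,A,39.9,3.1,,B,20
inoculated_mean,stalk,65,15.1,1.9,,A,52.7,7.1,,A,20
inoculated_mean,ear,65,15.5,1.9,,,31.8,4.5,,,20
inoculated_mean,plant_top,50,21.1,1.4,,A,175.7,13.5,,B,20
inoculated_mean,plant_top,65,17.5,1.9,,B,198.4,25.5,,A,20
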