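component,center_cm-1,fwhm_cm-1,amplitude,gauss_fraction
fibroin_An,961,14,0.6,0.7
fibroin_An,1230,30,0.3,0.7
fibroin_An,1508,25,0.55,0.7
fibroin_An,1620,28,1,0.7
fibroin_An,1699,20,0.25,0.7
fibroin_AGn,975,12,0.2,0.7
fibroin_AGn,998,12,0.35,0.7
fibroin_AGn,1230,30,0.3,0.7
fibroin_AGn,1508,25,0.55,0.7
fibroin_AGn,1620,28,0.95,0.7
fibroin_AGn,1699,20,0.2,0.7
helix_coil_feedstock,1245,28,0.35,0.7
helix_coil_feedstock,1270,22,0.2,0.7
helix_coil_feedstock,1308,20,0.3,0.7
helix_coil_feedstock,1547,30,0.6,0.7
helix_coil_feedstock,1642,35,1,0.7
sericin,1058,25,0.4,0.7
sericin,1075,22,0.25,0.7
sericin,1395,18,0.5,0.7
sericin,1535,30,0.45,0.7
sericin,1650,35,0.55,0.7
calcium_oxalate,779,12,0.6,0.7
calcium_oxalate,1315,18,0.9,0.7
calcium_oxalate,1620,25,0.35,0.7
phenolic,1035,25,0.25,0.7
phenolic,1103,25,0.5,0.7
phenolic,1733,20,0.25,0.7
water,1642,40,0.3,0.7
water,2130,150,0.08,0.7
water,3300,300,0.8,0.7
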