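case_id,age,sex,surgery,tumor_size_cm,ptnm,ajcc_stage,metastatic_sites,status,rnaseq,ihc
BEL-1T,46,F,nephrectomy,14,pT3bN2M0,3,,Died (12 months),Yes,No
BEL-2T,17,M,nephrectomy,5.5,pT3aN2M0,3,,NED,Yes,Yes
BEL-3T,42,F,nephrectomy,4.5,pT3aNxM0,3,,NED,Yes,Yes
BEL-4T,65,M,nephrectomy,7.5,pT3aN2M1,4,lung,Died (13 months),Yes,Yes
BEL-5T,56,M,partial nephrectomy,5,PT3aNxM0,3,,AWD,Yes,Yes
BEL-6T,49,M,nephrectomy,9,pT3aN1M0,3,,AWD,Yes,Yes
BEL-7T,28,F,nephrectomy,9,pT3aN2M1,4,paravertebral muscle,Died (26 months),Yes,No
BEL-8T,64,M,nephrectomy,3,pT4bN1M1,4,"liver, adrenal gland",AWD,Yes,No
BEL-9T,67,M,nephrectomy,8.7,pT3bN1M1,4,bone,Died (10 months),Yes,Yes
BEL-10T,60,F,nephrectomy,6.5,pT3N2M0,3,,AWD,Yes,Yes
BEL-11T,63,M,nephrectomy,7,pT2NxM0,2,,NED,Yes,No
BEL-12T,73,M,nephrectomy,11,pT3bNxM1,4,liver and lung,Died (9 months),No,Yes
BEL-13T,71,M,nephrectomy,9,T3aN0M0,3,,AWD,No,Yes
BEL-14T,63,M,nephrectomy,8,T3aNxM1,4,lung and bone,AWD,No,No
BEL-17T,78,F,nephrectomy,6,T3N2M0,3,,AWD,No,Yes
BEL-18T,33,F,No,8,T3bN2M1,4,"lung, liver and bone",Died (11 months),No,Yes
BEL-19T,59,M,nephrectomy,8,T3bN2M1,4,"bone, lung",AWD,No,Yes
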