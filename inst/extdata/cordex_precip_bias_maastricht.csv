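rcm,gcm,p_bias_mm_yr,published_rank
CCLM4-8-17,CNRM-CERFACS-CNRM-CM5,145,8
CCLM4-8-17,ICHEC-EC-EARTH,8,1
CCLM4-8-17,MOHC-HadGEM2-ES,-174,9
CCLM4-8-17,MPI-M-MPI-ESM-LR,24,2
ALADIN53,CNRM-CERFACS-CNRM-CM5,550,14
HIRHAM5,ICHEC-EC-EARTH,323,12
HIRHAM5,MOHC-HadGEM2-ES,101,6
HIRHAM5,NCC-NorESM1-M,571,16
WRF331F,IPSL-IPSL-CM5A-MR,726,18
RACMO22E,ICHEC-EC-EARTH,99,5
RACMO22E,MOHC-HadGEM2-ES,36,3
REMO2009,MPI-M-MPI-ESM-LR,225,10
ALARO-0,CNRM-CERFACS-CNRM-CM5,560,15
RCA4,CNRM-CERFACS-CNRM-CM5,319,11
RCA4,ICHEC-EC-EARTH,386,13
RCA4,IPSL-IPSL-CM5A-MR,691,17
RCA4,MOHC-HadGEM2-ES,111,7
RCA4,MPI-M-MPI-ESM-LR,70,4
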