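index,reference,d_plus1,d_plus1.5,d_plus2,d_plus3,d_plus4
T,8.17,1.13,1.14,1.81,3.15,4.49
TXx,30.98,0.82,1.66,1.34,5.24,6.30
TNn,-12.73,6.75,3.34,5.94,8.27,10.21
frost_days,103,-22,-14.8,-36.4,-59,-76.2
summer_days,11.4,4,12.2,8.6,26.2,36.6
GSL,225.6,9.6,20,33.6,45.8,80
PRCPTOT,771.09,-81.32,-57.2,25.12,-23.14,-136.05
Rx1day,14.38,-0.2,0.35,1.92,2.34,0.5
R10mm,14.6,0,-1,3.2,3.6,-1.2
CDD,17.2,2.4,9.6,1.6,7.2,11.8
CWD,9.6,-0.2,1.2,1.4,0,-1.8
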