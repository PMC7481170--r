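threshold,start,end
0,1951,1955
1,2011,2015
1.5,2028,2032
2,2043,2047
3,2067,2071
4,2091,2095
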