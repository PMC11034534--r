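characteristic,level,desert_n,other_n,desert_pct_printed,other_pct_printed
urbanicity,urban,2692,19972,57.5,25.4
urbanicity,suburban,204,30264,4.4,38.4
urbanicity,rural,1783,28487,38.1,36.2
pharmacies_per_tract,0,4421,43249,94.5,54.9
pharmacies_per_tract,1,34,14852,0.7,18.9
pharmacies_per_tract,2+,224,20622,4.8,26.2
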