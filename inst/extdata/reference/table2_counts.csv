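characteristic,level,desert_n,other_n,desert_pct_printed,other_pct_printed,p_printed
urbanicity,urban,179,15986,60.9,26.6,<.001
urbanicity,suburban,8,26922,2.7,44.7,
urbanicity,rural,107,17206,36.4,28.6,
urbanicity,na_no_population,0,61,0,0.1,
ownership,independent,121,22010,41.2,36.6,<.001
ownership,chain,165,37371,56.1,62.1,
ownership,franchise,3,659,1.0,1.1,
ownership,government,5,135,1.7,0.2,
immunization,yes,221,48510,75.2,80.6,.051
ada_accessible,yes,290,59429,98.6,98.8,1.000
multidose_packaging,yes,73,12056,24.8,20.0,.087
emergency_24h,yes,82,17841,27.9,29.6,.621
walk_in_clinic,yes,40,3923,13.6,6.5,<.001
compounding,yes,172,37230,58.5,61.9,.335
dme,yes,219,46742,74.5,77.7,.323
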