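quantity,value
n_tracts_total,84414
n_desert,4679
n_not_desert,78723
n_unclassified_no_income,446
n_unclassified_zero_pop,566
n_additional_low_access,7536
n_pharmacies_total,60475
n_pharmacies_in_deserts,294
desert_tracts_with_zero_pharmacies,4421
pct_desert_tracts_printed,5.5
pct_not_desert_tracts_printed,93.3
pct_unclassified_no_income_printed,0.5
pct_unclassified_zero_pop_printed,0.7
pct_pharmacies_in_deserts_printed,0.5
pct_desert_zero_pharmacies_printed,94.5
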