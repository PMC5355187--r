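# toy diet/interaction reference for a reintroduced agouti (fictitious records)
# 10 plants, 8 of them present in toy_flora.csv -> credit0 = 8, 4 flagged
animal_id,plant_id,source
agouti,  Astrocaryum   aculeatissimum,lit_a
agouti,Sterculia chicha,lit_a
agouti,Joannesia princeps,lit_b
agouti,Lecythis pisonis,lit_b
agouti,Ficus insipida,lit_c
agouti,Inga edulis,lit_c
agouti,Eugenia brasiliensis,lit_c
agouti,Guarea guidonia,lit_d
agouti,Bertholletia excelsa,lit_d
agouti,Hymenaea courbaril,lit_d
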