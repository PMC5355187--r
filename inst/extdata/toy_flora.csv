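# toy focal-area flora list (fictitious community, agouti-style case)
# documented ground truth: 12 species, 8 shared with toy_reference.csv
species_id,large_seeded_reliant
Astrocaryum aculeatissimum,true
Sterculia chicha,true
Joannesia princeps,true
Lecythis pisonis,true
Cariniana legalis,false
Ficus insipida,false
Cecropia glaziovii,false
Inga edulis,false
Eugenia brasiliensis,false
Miconia cinnamomifolia,false
Guarea guidonia,false
Piptadenia gonoacantha,false
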