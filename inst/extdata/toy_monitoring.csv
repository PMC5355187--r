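# toy post-release monitoring log (fictitious events)
# 6 eligible first observations within 15 months; 1 repeat; 1 unexpected
# (cecropia glaziovii is not in the diet reference); 1 event beyond month 15
time_months,plant_id,evidence
0.8,Astrocaryum aculeatissimum,fruit_consumption
2.1,Astrocaryum aculeatissimum,seed_burial
3.5,Sterculia chicha,fruit_consumption
4.0,Cecropia glaziovii,other
5.0,Joannesia princeps,seed_burial
6.2,Ficus insipida,fruit_consumption
9.4,Inga edulis,fruit_consumption
14.2,Eugenia brasiliensis,fruit_consumption
16.5,Guarea guidonia,fruit_consumption
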