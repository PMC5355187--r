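# synthetic emulation of an agouti-style reintroduction monitoring study
# generated by ecocredit::generate_scenario(synthetic_scenario(seed = 1))
# ground truth: credit0 = 65, 23 large-seeded-reliant, 24 species observed <= 15 months
time_months,plant_id,evidence
0.646651525813971,plant_0006,seed_burial
0.774816632706113,plant_0014,seed_burial
1.42286783200689,plant_0250,other
1.86017883929962,plant_0001,seed_burial
1.88385937684313,plant_0043,fruit_consumption
2.35613921859447,plant_0055,fruit_consumption
3.17708493600052,plant_0029,fruit_consumption
3.54771409183741,plant_0004,seed_burial
4.37106208551673,plant_0007,seed_burial
4.79743557109944,plant_0011,seed_burial
4.82964934231437,plant_0005,seed_burial
4.87539697693448,plant_0028,fruit_consumption
4.98589324899374,plant_0048,fruit_consumption
5.19883294474354,plant_0024,fruit_consumption
5.62824796303175,plant_0199,other
6.01053634445823,plant_0026,fruit_consumption
6.56819705583525,plant_0044,fruit_consumption
6.92327760974877,plant_0127,other
6.92665945236605,plant_0029,fruit_consumption
7.38894181209616,plant_0103,other
7.47030456770306,plant_0014,fruit_consumption
7.8088395004473,plant_0001,seed_burial
7.882973729608,plant_0022,seed_burial
8.66063483574753,plant_0030,fruit_consumption
8.69607025738827,plant_0037,fruit_consumption
9.37212782934558,plant_0029,fruit_consumption
10.1184572214649,plant_0009,seed_burial
10.3049747669869,plant_0027,fruit_consumption
10.4855896539788,plant_0013,fruit_consumption
11.0015963485334,plant_0016,seed_burial
11.6140345351212,plant_0014,fruit_consumption
12.5249249288534,plant_0012,fruit_consumption
13.2131658608017,plant_0059,fruit_consumption
14.0456300131564,plant_0014,seed_burial
14.088434564873,plant_0005,seed_burial
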