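# synthetic emulation of an agouti-style reintroduction monitoring study
# generated by ecocredit::generate_scenario(synthetic_scenario(seed = 1))
# ground truth: credit0 = 65, 23 large-seeded-reliant, 24 species observed <= 15 months
animal_id,plant_id
reintroduced_animal,plant_0001
reintroduced_animal,plant_0002
reintroduced_animal,plant_0003
reintroduced_animal,plant_0004
reintroduced_animal,plant_0005
reintroduced_animal,plant_0006
reintroduced_animal,plant_0007
reintroduced_animal,plant_0008
reintroduced_animal,plant_0009
reintroduced_animal,plant_0010
reintroduced_animal,plant_0011
reintroduced_animal,plant_0012
reintroduced_animal,plant_0013
reintroduced_animal,plant_0014
reintroduced_animal,plant_0015
reintroduced_animal,plant_0016
reintroduced_animal,plant_0017
reintroduced_animal,plant_0018
reintroduced_animal,plant_0019
reintroduced_animal,plant_0020
reintroduced_animal,plant_0021
reintroduced_animal,plant_0022
reintroduced_animal,plant_0023
reintroduced_animal,plant_0024
reintroduced_animal,plant_0025
reintroduced_animal,plant_0026
reintroduced_animal,plant_0027
reintroduced_animal,plant_0028
reintroduced_animal,plant_0029
reintroduced_animal,plant_0030
reintroduced_animal,plant_0031
reintroduced_animal,plant_0032
reintroduced_animal,plant_0033
reintroduced_animal,plant_0034
reintroduced_animal,plant_0035
reintroduced_animal,plant_0036
reintroduced_animal,plant_0037
reintroduced_animal,plant_0038
reintroduced_animal,plant_0039
reintroduced_animal,plant_0040
reintroduced_animal,plant_0041
reintroduced_animal,plant_0042
reintroduced_animal,plant_0043
reintroduced_animal,plant_0044
reintroduced_animal,plant_0045
reintroduced_animal,plant_0046
reintroduced_animal,plant_0047
reintroduced_animal,plant_0048
reintroduced_animal,plant_0049
reintroduced_animal,plant_0050
reintroduced_animal,plant_0051
reintroduced_animal,plant_0052
reintroduced_animal,plant_0053
reintroduced_animal,plant_0054
reintroduced_animal,plant_0055
reintroduced_animal,plant_0056
reintroduced_animal,plant_0057
reintroduced_animal,plant_0058
reintroduced_animal,plant_0059
reintroduced_animal,plant_0060
reintroduced_animal,plant_0061
reintroduced_animal,plant_0062
reintroduced_animal,plant_0063
reintroduced_animal,plant_0064
reintroduced_animal,plant_0065
reintroduced_animal,plant_0301
reintroduced_animal,plant_0302
reintroduced_animal,plant_0303
reintroduced_animal,plant_0304
reintroduced_animal,plant_0305
reintroduced_animal,plant_0306
reintroduced_animal,plant_0307
reintroduced_animal,plant_0308
reintroduced_animal,plant_0309
reintroduced_animal,plant_0310
reintroduced_animal,plant_0311
reintroduced_animal,plant_0312
reintroduced_animal,plant_0313
reintroduced_animal,plant_0314
reintroduced_animal,plant_0315
reintroduced_animal,plant_0316
reintroduced_animal,plant_0317
reintroduced_animal,plant_0318
reintroduced_animal,plant_0319
reintroduced_animal,plant_0320
reintroduced_animal,plant_0321
reintroduced_animal,plant_0322
reintroduced_animal,plant_0323
reintroduced_animal,plant_0324
reintroduced_animal,plant_0325
reintroduced_animal,plant_0326
reintroduced_animal,plant_0327
reintroduced_animal,plant_0328
reintroduced_animal,plant_0329
reintroduced_animal,plant_0330
reintroduced_animal,plant_0331
reintroduced_animal,plant_0332
reintroduced_animal,plant_0333
reintroduced_animal,plant_0334
reintroduced_animal,plant_0335
reintroduced_animal,plant_0336
reintroduced_animal,plant_0337
reintroduced_animal,plant_0338
reintroduced_animal,plant_0339
reintroduced_animal,plant_0340
reintroduced_animal,plant_0341
reintroduced_animal,plant_0342
reintroduced_animal,plant_0343
reintroduced_animal,plant_0344
reintroduced_animal,plant_0345
reintroduced_animal,plant_0346
reintroduced_animal,plant_0347
reintroduced_animal,plant_0348
reintroduced_animal,plant_0349
reintroduced_animal,plant_0350
reintroduced_animal,plant_0351
reintroduced_animal,plant_0352
reintroduced_animal,plant_0353
reintroduced_animal,plant_0354
reintroduced_animal,plant_0355
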