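# synthetic emulation of an agouti-style reintroduction monitoring study
# generated by ecocredit::generate_scenario(synthetic_scenario(seed = 1))
# ground truth: credit0 = 65, 23 large-seeded-reliant, 24 species observed <= 15 months
species_id,large_seeded_reliant
plant_0001,TRUE
plant_0002,TRUE
plant_0003,TRUE
plant_0004,TRUE
plant_0005,TRUE
plant_0006,TRUE
plant_0007,TRUE
plant_0008,TRUE
plant_0009,TRUE
plant_0010,TRUE
plant_0011,TRUE
plant_0012,TRUE
plant_0013,TRUE
plant_0014,TRUE
plant_0015,TRUE
plant_0016,TRUE
plant_0017,TRUE
plant_0018,TRUE
plant_0019,TRUE
plant_0020,TRUE
plant_0021,TRUE
plant_0022,TRUE
plant_0023,TRUE
plant_0024,FALSE
plant_0025,FALSE
plant_0026,FALSE
plant_0027,FALSE
plant_0028,FALSE
plant_0029,FALSE
plant_0030,FALSE
plant_0031,FALSE
plant_0032,FALSE
plant_0033,FALSE
plant_0034,FALSE
plant_0035,FALSE
plant_0036,FALSE
plant_0037,FALSE
plant_0038,FALSE
plant_0039,FALSE
plant_0040,FALSE
plant_0041,FALSE
plant_0042,FALSE
plant_0043,FALSE
plant_0044,FALSE
plant_0045,FALSE
plant_0046,FALSE
plant_0047,FALSE
plant_0048,FALSE
plant_0049,FALSE
plant_0050,FALSE
plant_0051,FALSE
plant_0052,FALSE
plant_0053,FALSE
plant_0054,FALSE
plant_0055,FALSE
plant_0056,FALSE
plant_0057,FALSE
plant_0058,FALSE
plant_0059,FALSE
plant_0060,FALSE
plant_0061,FALSE
plant_0062,FALSE
plant_0063,FALSE
plant_0064,FALSE
plant_0065,FALSE
plant_0066,FALSE
plant_0067,FALSE
plant_0068,FALSE
plant_0069,FALSE
plant_0070,FALSE
plant_0071,FALSE
plant_0072,FALSE
plant_0073,FALSE
plant_0074,FALSE
plant_0075,FALSE
plant_0076,FALSE
plant_0077,FALSE
plant_0078,FALSE
plant_0079,FALSE
plant_0080,FALSE
plant_0081,FALSE
plant_0082,FALSE
plant_0083,FALSE
plant_0084,FALSE
plant_0085,FALSE
plant_0086,FALSE
plant_0087,FALSE
plant_0088,FALSE
plant_0089,FALSE
plant_0090,FALSE
plant_0091,FALSE
plant_0092,FALSE
plant_0093,FALSE
plant_0094,FALSE
plant_0095,FALSE
plant_0096,FALSE
plant_0097,FALSE
plant_0098,FALSE
plant_0099,FALSE
plant_0100,FALSE
plant_0101,FALSE
plant_0102,FALSE
plant_0103,FALSE
plant_0104,FALSE
plant_0105,FALSE
plant_0106,FALSE
plant_0107,FALSE
plant_0108,FALSE
plant_0109,FALSE
plant_0110,FALSE
plant_0111,FALSE
plant_0112,FALSE
plant_0113,FALSE
plant_0114,FALSE
plant_0115,FALSE
plant_0116,FALSE
plant_0117,FALSE
plant_0118,FALSE
plant_0119,FALSE
plant_0120,FALSE
plant_0121,FALSE
plant_0122,FALSE
plant_0123,FALSE
plant_0124,FALSE
plant_0125,FALSE
plant_0126,FALSE
plant_0127,FALSE
plant_0128,FALSE
plant_0129,FALSE
plant_0130,FALSE
plant_0131,FALSE
plant_0132,FALSE
plant_0133,FALSE
plant_0134,FALSE
plant_0135,FALSE
plant_0136,FALSE
plant_0137,FALSE
plant_0138,FALSE
plant_0139,FALSE
plant_0140,FALSE
plant_0141,FALSE
plant_0142,FALSE
plant_0143,FALSE
plant_0144,FALSE
plant_0145,FALSE
plant_0146,FALSE
plant_0147,FALSE
plant_0148,FALSE
plant_0149,FALSE
plant_0150,FALSE
plant_0151,FALSE
plant_0152,FALSE
plant_0153,FALSE
plant_0154,FALSE
plant_0155,FALSE
plant_0156,FALSE
plant_0157,FALSE
plant_0158,FALSE
plant_0159,FALSE
plant_0160,FALSE
plant_0161,FALSE
plant_0162,FALSE
plant_0163,FALSE
plant_0164,FALSE
plant_0165,FALSE
plant_0166,FALSE
plant_0167,FALSE
plant_0168,FALSE
plant_0169,FALSE
plant_0170,FALSE
plant_0171,FALSE
plant_0172,FALSE
plant_0173,FALSE
plant_0174,FALSE
plant_0175,FALSE
plant_0176,FALSE
plant_0177,FALSE
plant_0178,FALSE
plant_0179,FALSE
plant_0180,FALSE
plant_0181,FALSE
plant_0182,FALSE
plant_0183,FALSE
plant_0184,FALSE
plant_0185,FALSE
plant_0186,FALSE
plant_0187,FALSE
plant_0188,FALSE
plant_0189,FALSE
plant_0190,FALSE
plant_0191,FALSE
plant_0192,FALSE
plant_0193,FALSE
plant_0194,FALSE
plant_0195,FALSE
plant_0196,FALSE
plant_0197,FALSE
plant_0198,FALSE
plant_0199,FALSE
plant_0200,FALSE
plant_0201,FALSE
plant_0202,FALSE
plant_0203,FALSE
plant_0204,FALSE
plant_0205,FALSE
plant_0206,FALSE
plant_0207,FALSE
plant_0208,FALSE
plant_0209,FALSE
plant_0210,FALSE
plant_0211,FALSE
plant_0212,FALSE
plant_0213,FALSE
plant_0214,FALSE
plant_0215,FALSE
plant_0216,FALSE
plant_0217,FALSE
plant_0218,FALSE
plant_0219,FALSE
plant_0220,FALSE
plant_0221,FALSE
plant_0222,FALSE
plant_0223,FALSE
plant_0224,FALSE
plant_0225,FALSE
plant_0226,FALSE
plant_0227,FALSE
plant_0228,FALSE
plant_0229,FALSE
plant_0230,FALSE
plant_0231,FALSE
plant_0232,FALSE
plant_0233,FALSE
plant_0234,FALSE
plant_0235,FALSE
plant_0236,FALSE
plant_0237,FALSE
plant_0238,FALSE
plant_0239,FALSE
plant_0240,FALSE
plant_0241,FALSE
plant_0242,FALSE
plant_0243,FALSE
plant_0244,FALSE
plant_0245,FALSE
plant_0246,FALSE
plant_0247,FALSE
plant_0248,FALSE
plant_0249,FALSE
plant_0250,FALSE
plant_0251,FALSE
plant_0252,FALSE
plant_0253,FALSE
plant_0254,FALSE
plant_0255,FALSE
plant_0256,FALSE
plant_0257,FALSE
plant_0258,FALSE
plant_0259,FALSE
plant_0260,FALSE
plant_0261,FALSE
plant_0262,FALSE
plant_0263,FALSE
plant_0264,FALSE
plant_0265,FALSE
plant_0266,FALSE
plant_0267,FALSE
plant_0268,FALSE
plant_0269,FALSE
plant_0270,FALSE
plant_0271,FALSE
plant_0272,FALSE
plant_0273,FALSE
plant_0274,FALSE
plant_0275,FALSE
plant_0276,FALSE
plant_0277,FALSE
plant_0278,FALSE
plant_0279,FALSE
plant_0280,FALSE
plant_0281,FALSE
plant_0282,FALSE
plant_0283,FALSE
plant_0284,FALSE
plant_0285,FALSE
plant_0286,FALSE
plant_0287,FALSE
plant_0288,FALSE
plant_0289,FALSE
plant_0290,FALSE
plant_0291,FALSE
plant_0292,FALSE
plant_0293,FALSE
plant_0294,FALSE
plant_0295,FALSE
plant_0296,FALSE
plant_0297,FALSE
plant_0298,FALSE
plant_0299,FALSE
plant_0300,FALSE
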