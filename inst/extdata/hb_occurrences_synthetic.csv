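longitude,latitude,allele
-3.3762,58.3865,HbS
-4.447,58.3763,HbS
-4.2594,58.2548,HbS
-1.2684,58.1469,HbS
0.7538,58.0047,HbS
-2.8936,57.9372,HbS
0.9321,57.9019,HbS
-4.0392,57.8601,HbS
-0.3046,57.7168,HbS
0.0995,57.5903,HbS
1.1848,57.5499,HbS
-0.7282,57.438,HbS
-2.6948,57.4227,HbS
-0.5555,57.344,HbS
-4.5742,57.0531,HbS
-4.1337,56.82,HbS
0.9745,56.8014,HbS
-0.4398,56.797,HbS
-4.6034,56.7832,HbS
0.637,56.7144,HbS
-2.2165,56.5847,HbS
-3.7925,56.4378,HbS
0.1484,56.398,HbS
-4.5723,56.2139,HbS
-5.1088,56.1843,HbS
-1.783,56.1749,HbS
-0.8434,55.8404,HbS
-3.0573,55.6755,HbS
-3.3693,55.5359,HbS
0.7382,55.4974,HbS
-5.1615,55.4102,HbS
1.1617,55.3869,HbS
-0.42,55.3178,HbS
-1.4081,55.308,HbS
-1.1902,55.2835,HbS
1.2109,55.2776,HbS
-0.8705,55.0121,HbS
-4.959,54.9398,HbS
-2.8526,54.9194,HbS
-4.383,54.6187,HbS
-4.959,54.9398,HbF
-2.8526,54.9194,HbF
-4.383,54.6187,HbF
-3.2632,54.5855,HbF
-4.2941,54.5355,HbF
1.1908,54.1781,HbF
0.3777,53.9808,HbF
-2.0522,53.976,HbF
-2.6074,53.8588,HbF
1.033,53.8495,HbF
-1.7265,53.7552,HbF
-0.6609,53.7511,HbF
-2.2244,53.55,HbF
-2.2835,53.3345,HbF
-3.7691,53.2328,HbF
-5.3396,53.1748,HbF
-4.1628,53.1591,HbF
-1.9576,52.9117,HbF
0.0185,52.6722,HbF
-1.8254,52.5391,HbF
-4.1441,52.4096,HbF
-0.5048,52.1085,HbF
-3.8176,52.0947,HbF
-4.7825,52.0673,HbF
-0.7108,52.0542,HbF
-1.9519,52.0426,HbF
1.0191,52.0268,HbF
1.3082,51.9522,HbF
-3.5303,51.9205,HbF
-4.9136,51.8769,HbF
-4.3184,51.8614,HbF
-3.6897,51.8407,HbF
1.3765,51.8242,HbF
-0.9559,51.7614,HbF
-5.0574,51.7546,HbF
-5.4892,51.6864,HbF
-0.3872,51.5314,HbF
-3.1014,51.5181,HbF
1.3004,51.4638,HbF
-2.8498,51.3958,HbF
-2.1743,51.3785,HbF
-5.1854,51.3358,HbF
0.9791,51.2073,HbF
-1.5967,51.1708,HbF
0.2659,51.1161,HbF
-4.672,51.1121,HbF
-2.3408,50.916,HbF
-0.23,50.891,HbF
-0.7641,50.8849,HbF
-2.5809,50.7443,HbF
-1.4194,50.4589,HbF
-2.6959,50.3914,HbF
-1.8334,50.3534,HbF
-5.4227,50.3046,HbF
-3.9015,50.2286,HbF
-4.8537,50.2232,HbF
-5.3942,50.2005,HbF
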