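metabolite,HC_vs_PC_I_II,HC_vs_PC_III,HC_vs_PC_IV,DM2_vs_PC_I_II,DM2_vs_PC_III,DM2_vs_PC_IV
3-hydroxyisovalerate,0.0211,0.0377,0.0190,0.0231,0.0452,0.0187
creatine,0.0001,0.0001,0.0001,0.0003,0.0006,0.0004
fumarate,0.0026,0.0014,0.0005,0.0122,0.0160,0.0052
gluconate,0.0285,0.0039,0.0003,0.0003,0.0000,0.0000
lysine,0.0000,0.0000,0.0004,0.0059,0.0055,0.0269
mannose,0.0000,0.0001,0.0000,0.0004,0.0041,0.0000
N-acetylcysteine,0.0047,0.0007,0.0009,0.0428,0.0123,0.0204
proline,0.0187,0.0100,0.0313,0.0059,0.0032,0.0187
propionate,0.0147,0.0279,0.0089,0.0004,0.0032,0.0000
3-hydroxybutyrate,0.0085,0.0008,0.0001,0.0030,0.0304,0.0950
alanine,0.1401,0.1352,0.0002,0.1651,0.2362,0.0021
glutamate,0.0497,0.2666,0.0792,0.1598,0.3952,0.1838
valine,0.4274,0.3973,0.0444,0.7576,0.8943,0.2436
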