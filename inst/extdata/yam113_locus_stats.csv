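locus,na,ne,ho,he,nei,shannon_i,pic
Do2,4,2.0954,0.2054,0.5251,0.5228,0.9131,0.4608
Do22,6,2.6809,0.9115,0.6298,0.6270,1.1951,0.5710
Do7,8,2.5391,0.8761,0.6088,0.6062,1.1067,0.5268
SSR1,8,3.5314,0.9459,0.7201,0.7168,1.5555,0.6850
SSR13,6,4.1527,0.9820,0.7626,0.7592,1.5725,0.7224
SSR17,6,2.4968,0.9196,0.6022,0.5995,1.0654,0.5201
SSR183,4,2.6411,0.9273,0.6242,0.6214,1.0771,0.5457
SSR214,4,2.4354,0.9735,0.5920,0.5894,0.9928,0.5066
SSR226,4,2.3483,0.8053,0.5767,0.5742,0.9408,0.4808
SSR232,6,2.4322,0.9823,0.5915,0.5888,1.0245,0.5026
SSR275,15,4.7293,0.6460,0.7921,0.7886,1.9531,0.7696
SSR277,7,3.0859,1.0000,0.6790,0.6759,1.3582,0.6279
SSR362,4,2.7432,0.9640,0.6383,0.6355,1.0792,0.5609
SSR368,5,2.1659,0.9469,0.5407,0.5383,0.8751,0.4347
SSR373,9,3.1393,0.6822,0.6847,0.6815,1.3066,0.6214
SSR377,4,2.0068,0.6991,0.5039,0.5017,0.7637,0.3925
SSR41,5,2.5171,0.9643,0.6054,0.6027,1.0665,0.5303
SSR53,7,2.9799,0.9554,0.6674,0.6644,1.3283,0.6186
SSR92,6,2.6806,0.9732,0.6298,0.6270,1.1697,0.5608
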