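image,point,x_mm,y_mm,z_mm
1,1,3.4167,-22.2013,-2.6957
1,2,331.6863,-22.0400,-3.7915
1,3,4.6098,309.1427,1.7573
1,4,332.8794,309.3039,0.6615
1,5,3.6098,-21.9385,107.9271
1,6,331.8794,-21.7772,106.8313
1,7,4.8029,309.4055,112.3801
1,8,333.0724,309.5667,111.2843
2,1,2.9734,-29.8271,-17.7596
2,2,332.0465,-27.5075,-16.6379
2,3,2.2699,305.3511,-17.0817
2,4,331.3430,307.6706,-15.9600
2,5,3.0988,-24.7405,94.2014
2,6,332.1718,-22.4210,95.3231
2,7,2.3953,310.4376,94.8793
2,8,331.4683,312.7571,96.0010
3,1,7.3801,-30.8327,-32.4198
3,2,333.7592,-29.2687,-27.2289
3,3,9.9346,301.5044,-31.1614
3,4,336.3137,303.0685,-25.9705
3,5,7.8149,-28.1302,73.5445
3,6,334.1940,-26.5661,78.7354
3,7,10.3693,304.2070,74.8029
3,8,336.7485,305.7711,79.9938
4,1,-4.4250,-22.1707,-6.5618
4,2,327.7407,-21.7509,-8.7225
4,3,-4.2159,311.6391,-4.4026
4,4,327.9498,312.0588,-6.5633
4,5,-4.0413,-22.2377,106.3093
4,6,328.1243,-21.8180,104.1486
4,7,-3.8322,311.5720,108.4685
4,8,328.3335,311.9917,106.3078
5,1,0.4343,-33.2795,-32.1174
5,2,333.7756,-31.6846,-31.6177
5,3,1.3211,301.9878,-33.3221
5,4,334.6624,303.5827,-32.8224
5,5,0.9893,-30.9427,76.9555
5,6,334.3306,-29.3477,77.4553
5,7,1.8761,304.3246,75.7508
5,8,335.2174,305.9196,76.2505
6,1,-14.1576,-32.7423,-23.8992
6,2,308.7199,-34.2773,-26.0497
6,3,-16.6352,298.2377,-21.9366
6,4,306.2424,296.7028,-24.0871
6,5,-13.7173,-30.1729,85.4656
6,6,309.1603,-31.7078,83.3151
6,7,-16.1948,300.8072,87.4282
6,8,306.6827,299.2722,85.2777
7,1,-7.6836,-35.2270,-19.1140
7,2,330.7646,-33.7368,-18.2985
7,3,-8.3642,304.4994,-16.5283
7,4,330.0840,305.9896,-15.7128
7,5,-7.7841,-37.0440,92.8582
7,6,330.6641,-35.5538,93.6738
7,7,-8.4647,302.6823,95.4439
7,8,329.9835,304.1725,96.2594
8,1,16.5968,-32.3464,-22.5351
8,2,337.2910,-39.1214,-20.8741
8,3,34.2465,299.5795,-22.6286
8,4,354.9407,292.8044,-20.9676
8,5,16.5872,-26.0946,90.3929
8,6,337.2813,-32.8696,92.0538
8,7,34.2369,305.8313,90.2994
8,8,354.9310,299.0562,91.9603
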