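image,point,mask_mm,no_mask_mm
1,1,0.209,0.179
1,2,0.367,0.191
1,3,0.468,0.131
1,4,0.159,0.365
1,5,0.148,0.258
1,6,0.489,0.114
1,7,0.346,0.174
1,8,0.228,0.297
2,1,1.260,0.535
2,2,0.666,0.617
2,3,1.446,0.727
2,4,1.409,0.586
2,5,1.204,0.749
2,6,0.850,0.870
2,7,1.386,0.575
2,8,1.494,0.496
3,1,2.114,3.469
3,2,1.553,4.152
3,3,1.307,6.576
3,4,1.279,7.070
3,5,1.714,5.029
3,6,0.987,5.274
3,7,0.960,8.033
3,8,0.972,8.282
4,1,1.247,0.594
4,2,0.915,1.015
4,3,1.507,0.703
4,4,0.430,0.415
4,5,0.843,0.343
4,6,0.958,0.827
4,7,1.344,0.859
4,8,0.803,0.553
5,1,3.064,2.998
5,2,3.059,2.964
5,3,2.612,2.584
5,4,1.601,1.543
5,5,2.175,2.189
5,6,1.832,1.782
5,7,3.247,3.209
5,8,2.223,2.141
6,1,0.737,5.057
6,2,1.366,17.157
6,3,1.595,9.568
6,4,2.803,21.541
6,5,1.594,6.484
6,6,2.116,17.945
6,7,1.661,10.419
6,8,2.948,22.187
7,1,1.327,0.909
7,2,0.954,0.892
7,3,0.328,0.436
7,4,0.614,0.098
7,5,1.089,0.598
7,6,0.615,0.546
7,7,0.705,0.611
7,8,0.899,0.404
8,1,3.161,10.620
8,2,1.108,5.676
8,3,3.041,9.223
8,4,1.396,7.952
8,5,3.258,10.370
8,6,1.854,6.935
8,7,3.014,8.926
8,8,1.836,8.886
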