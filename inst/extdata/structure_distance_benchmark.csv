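image,structure,mask_mm_printed,no_mask_mm_printed
1,sylvian_aqueduct,5.925,4.921
1,anterior_commissure,14.583,14.198
1,right_lens,5.511,5.209
1,left_lens,4.254,4.191
1,pineal_gland,5.059,2.429
2,sylvian_aqueduct,13.588,17.526
2,anterior_commissure,13.094,17.487
2,right_lens,5.762,16.451
2,left_lens,4.291,12.683
2,pineal_gland,4.013,6.754
3,sylvian_aqueduct,14.668,14.41
3,anterior_commissure,0.994,2.719
3,right_lens,2.089,1.39
3,left_lens,1.299,1.468
3,pineal_gland,1.651,3.188
4,sylvian_aqueduct,3.696,3.458
4,anterior_commissure,4.738,4.86
4,right_lens,16.774,16.101
4,left_lens,26.282,24.544
4,pineal_gland,9.615,9.612
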