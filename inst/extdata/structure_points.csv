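image_set,image,structure,x_mm,y_mm,z_mm
ct,1,sylvian_aqueduct,1.619,132.161,128.294
ct,1,anterior_commissure,0.079,149.323,131.294
ct,1,right_lens,30.48,227.407,121.907
ct,1,left_lens,-39.392,221.421,120.383
ct,1,pineal_gland,1.399,132.381,139.294
ct,2,sylvian_aqueduct,1.719,130.778,-390.919
ct,2,anterior_commissure,0.31,145.902,-365.217
ct,2,right_lens,30.951,230.123,-365.558
ct,2,left_lens,-38.422,226.1,-367.741
ct,2,pineal_gland,2.155,125.729,-375.287
ct,3,sylvian_aqueduct,-0.001,133.384,-411.389
ct,3,anterior_commissure,-0.425,170.072,-410.326
ct,3,right_lens,29.609,225.447,-457.272
ct,3,left_lens,-36.389,224.62,-453.821
ct,3,pineal_gland,1.039,141.247,-398.385
ct,4,sylvian_aqueduct,6.398,149.516,-571.414
ct,4,anterior_commissure,-0.19,170.766,-565.312
ct,4,right_lens,-0.743,234.271,-598.263
ct,4,left_lens,-54.969,215.592,-584.7
ct,4,pineal_gland,9.875,147.018,-558.196
mri_mask,1,sylvian_aqueduct,-0.497,135.501,131.223
mri_mask,1,anterior_commissure,-2.628,159.994,140.26
mri_mask,1,right_lens,31.231,226.372,126.957
mri_mask,1,left_lens,-38.222,220.542,124.31
mri_mask,1,pineal_gland,-0.381,134.024,139.112
mri_mask,2,sylvian_aqueduct,-0.941,137.412,-374.917
mri_mask,2,anterior_commissure,-2.127,163.213,-365.627
mri_mask,2,right_lens,34.232,237.695,-379.789
mri_mask,2,left_lens,-36.479,233.46,-377.886
mri_mask,2,pineal_gland,-0.327,131.274,-372.335
mri_mask,3,sylvian_aqueduct,-0.139,146.147,-404.701
mri_mask,3,anterior_commissure,-2.833,169.993,-409.066
mri_mask,3,right_lens,28.638,225.725,-456.317
mri_mask,3,left_lens,-37.283,224.27,-452.711
mri_mask,3,pineal_gland,0.002,143.884,-399.845
mri_mask,4,sylvian_aqueduct,3.085,150.405,-571.851
mri_mask,4,anterior_commissure,-0.279,173.761,-569.139
mri_mask,4,right_lens,13.94,230.782,-603.875
mri_mask,4,left_lens,-46.124,228.076,-603.892
mri_mask,4,pineal_gland,5.151,144.134,-566.054
mri_no_mask,1,sylvian_aqueduct,-0.469,136.396,131.874
mri_no_mask,1,anterior_commissure,-2.491,160.081,140.798
mri_no_mask,1,right_lens,31.606,226.472,127.22
mri_no_mask,1,left_lens,-38.372,220.462,124.4
mri_no_mask,1,pineal_gland,0.05,131.032,134.609
mri_no_mask,2,sylvian_aqueduct,-0.435,134.905,-378.153
mri_no_mask,2,anterior_commissure,-2.048,158.782,-365.235
mri_no_mask,2,right_lens,33.893,231.655,-370.27
mri_no_mask,2,left_lens,-36.656,226.912,-371.566
mri_no_mask,2,pineal_gland,0.013,129.051,-375.979
mri_no_mask,3,sylvian_aqueduct,1.229,146.558,-405.057
mri_no_mask,3,anterior_commissure,-0.905,169.695,-409.541
mri_no_mask,3,right_lens,29.558,226.22,-455.332
mri_no_mask,3,left_lens,-36.204,224.27,-452.584
mri_no_mask,3,pineal_gland,1.401,141.552,-399.967
mri_no_mask,4,sylvian_aqueduct,3.03,151.037,-571.368
mri_no_mask,4,anterior_commissure,-0.098,173.599,-569.108
mri_no_mask,4,right_lens,14.847,230.98,-603.507
mri_no_mask,4,left_lens,-45.157,228.144,-605.603
mri_no_mask,4,pineal_gland,4.646,144.436,-565.84
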