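label,x_mm,y_mm,z_mm
1,0.0000,0.0000,0.0000
2,333.9870,0.0000,0.0000
3,0.0000,333.9870,0.0000
4,333.9870,333.9870,0.0000
5,0.0000,0.0000,112.0000
6,333.9870,0.0000,112.0000
7,0.0000,333.9870,112.0000
8,333.9870,333.9870,112.0000
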