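name,pattern,mode,human_mz,human_rt,human_auc,mouse_mz,mouse_rt,mouse_auc
Acetylcarnitine,down,positive,204.12197,1.161,0.7956,204.1219,1.138,0.9286
Mystamide,up,positive,228.2311,3.756,0.6715,228.23091,3.75,0.9578
Palmitamide,up,positive,256.2623,4.258,0.7247,256.26229,4.25,0.7857
Palmitoylcarnitine,down,positive,400.34047,5.558,0.6103,400.34014,5.514,0.9058
LysoPC(18:3),down,positive,518.32194,3.596,0.7287,518.32159,3.605,1.0000
LysoPC(18:2),down,positive,520.3374,3.863,0.6689,520.33689,3.844,0.7597
LysoPC(18:1),down,positive,522.35298,4.153,0.6081,522.35272,4.147,0.8474
LysoPC(22:6),down,positive,568.3375,3.8,0.6431,568.33677,3.785,0.7890
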