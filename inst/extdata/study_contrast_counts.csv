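contrast,differential_features,level2_annotations,validated_compounds
N1_vs_N2T,1250,63,23
N2T_vs_N3,603,26,5
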