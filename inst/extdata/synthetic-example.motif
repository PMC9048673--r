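>ACGTAC	synthetic_example_motif	0
0.880	0.040	0.040	0.040
0.040	0.880	0.040	0.040
0.040	0.040	0.880	0.040
0.040	0.040	0.040	0.880
0.880	0.040	0.040	0.040
0.040	0.880	0.040	0.040
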