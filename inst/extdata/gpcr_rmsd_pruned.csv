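pdb_id,hybrid_af_templates,hybrid_human_af,af3,af2
6D9H,0.879,0.871,0.938,0.879
7AUE,1.126,1.028,1.095,1.028
7F4D,1.121,0.922,1.034,0.922
7F53,0.949,0.919,0.777,0.914
7LD3,0.857,0.905,0.992,0.914
7PIU,0.960,0.929,0.804,0.903
7WKD,1.008,0.990,1.017,0.930
7X1T,1.061,1.060,1.021,1.057
8EFB,0.807,0.813,1.018,1.067
8F7Q,0.860,0.864,1.107,1.035
8F7W,1.105,1.118,1.109,0.858
8F7X,0.954,1.032,1.008,1.118
8HDO,1.016,1.006,0.959,1.033
8HTI,1.022,1.048,0.874,0.998
8ZPS,1.053,1.059,1.107,1.071
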