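pdb_id,hybrid_af_templates,hybrid_human_af,af3,af2
6D9H,2.594,2.615,2.630,2.594
7AUE,1.715,1.760,2.606,1.760
7F4D,1.698,1.403,1.841,1.403
7F53,1.145,1.767,1.741,1.766
7LD3,2.374,2.490,2.554,2.491
7PIU,2.357,1.538,2.263,1.537
7WKD,1.959,1.961,1.928,3.359
7X1T,2.078,2.080,2.057,2.081
8EFB,1.539,1.520,3.173,1.526
8F7Q,1.554,1.588,3.096,1.560
8F7W,2.715,2.725,3.168,2.727
8F7X,1.835,3.010,3.205,3.010
8HDO,3.428,3.333,3.279,3.340
8HTI,1.903,1.905,2.159,2.008
8ZPS,2.454,2.492,2.565,2.492
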