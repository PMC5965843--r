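parameter,value,comment
b_n_ca,1.458,N-CA bond length (A)
b_ca_c,1.525,CA-C bond length (A)
b_c_n,1.329,C-N peptide bond length (A)
b_c_o,1.231,C=O bond length (A)
b_ca_cb,1.521,CA-CB bond length (A)
a_c_n_ca,121.7,C-N-CA bond angle (deg)
a_n_ca_c,111.2,N-CA-C bond angle (deg)
a_ca_c_n,116.2,CA-C-N bond angle (deg)
a_ca_c_o,120.8,CA-C=O bond angle (deg)
a_n_ca_cb,110.4,N-CA-CB bond angle (deg)
t_c_n_ca_cb,-123.0,improper torsion C-N-CA-CB fixing L chirality (deg)
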