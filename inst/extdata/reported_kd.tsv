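id	anisotropy_kd_nM	anisotropy_censored	apce_kd_nM
A1	2200	FALSE	390
A3	9100	FALSE	500
B10	280	FALSE	870
D3	26000	FALSE	NA
L1	750000	TRUE	300
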