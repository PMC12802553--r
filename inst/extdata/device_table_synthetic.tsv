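qubit	T1_us	T2_us	err_1q	err_2q	dur_1q_ns	dur_2q_ns	p01	p10
0	182.4	121.7	0.00021	0.00139	32	68	0.011	0.019
1	167.9	138.2	0.00025	0.00152	32	68	0.009	0.022
2	201.3	110.5	0.00019	0.00141	32	68	0.012	0.018
3	155.0	129.8	0.00028	0.00158	32	68	0.010	0.021
4	190.6	142.1	0.00022	0.00144	32	68	0.013	0.017
5	173.2	118.9	0.00024	0.00149	32	68	0.008	0.023
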