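population	n_total	tall	semi_dwarf	dwarf	expected_ratio
3529	60	60	0	0	1:0:0
ndf-2	60	0	0	60	0:0:1
F1	56	0	56	0	0:1:0
F2	576	139	268	159	1:2:1
B11	164	73	91	0	1:1:0
B12	234	0	127	107	0:1:1
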