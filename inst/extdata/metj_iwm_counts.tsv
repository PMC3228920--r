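base	count_1	count_2	count_3	count_4
A	634	156	721	37
C	6	25	84	573
G	135	560	27	4
T	57	91	0	218
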