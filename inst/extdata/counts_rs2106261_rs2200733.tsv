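population	genotype_a	genotype_b	n_case	n_control
discovery	GG	CC	44	230
discovery	GG	CT	106	475
discovery	GG	TT	83	206
discovery	AG	CC	21	206
discovery	AG	CT	117	420
discovery	AG	TT	99	243
discovery	AA	CC	13	51
discovery	AA	CT	40	115
discovery	AA	TT	46	50
replication1	GG	CC	43	199
replication1	GG	CT	129	413
replication1	GG	TT	87	176
replication1	AG	CC	44	166
replication1	AG	CT	139	378
replication1	AG	TT	96	163
replication1	AA	CC	10	47
replication1	AA	CT	47	104
replication1	AA	TT	46	46
replication2	GG	CC	44	176
replication2	GG	CT	161	379
replication2	GG	TT	108	197
replication2	AG	CC	56	162
replication2	AG	CT	189	404
replication2	AG	TT	124	160
replication2	AA	CC	15	30
replication2	AA	CT	57	74
replication2	AA	TT	56	45
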