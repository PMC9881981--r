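kmer	level_mean	level_stdv
AA	80	1.5
AC	81	1.5
AG	82	1.5
AT	83	1.5
CA	84	1.5
CC	85	1.5
CG	86	1.5
CT	87	1.5
GA	88	1.5
GC	89	1.5
GG	90	1.5
GT	91	1.5
TA	92	1.5
TC	93	1.5
TG	94	1.5
TT	95	1.5
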