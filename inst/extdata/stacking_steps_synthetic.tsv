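# source: synthetic-placeholder
step	dg
AA	5.20
AG	5.25
GA	5.30
GG	5.35
AC	3.60
AT	3.65
GC	3.70
GT	3.75
CA	2.60
CG	2.65
TA	2.70
TG	2.75
CC	1.60
CT	1.65
TC	1.70
TT	1.75
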