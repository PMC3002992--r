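# Published single-gene knockout attractor counts for the Th1/Th2 network:
# per knocked-out gene and stimulation modality, the total number of
# attractors, the static (length 1) / dynamical (length > 1) split, and the
# maximal cycle length. Gene labels as printed in the source; resolved via
# the alias table (PLCPG -> PLCG).
gene	modality	attractors	static	dynamical	max_length
COT	temporary	4	3	1	3
COT	persisting	1186	898	288	3
GATA3	temporary	3	3	0	1
GATA3	persisting	322	322	0	1
IKBKB	temporary	4	3	1	3
IKBKB	persisting	594	450	144	3
IRAK	temporary	4	3	1	3
IRAK	persisting	612	452	160	3
IRF4	temporary	9	3	6	5
IRF4	persisting	604	450	154	5
ITK	temporary	4	3	1	3
ITK	persisting	1188	900	288	3
JAK1	temporary	4	3	1	3
JAK1	persisting	594	450	144	3
JAK3	temporary	3	3	0	1
JAK3	persisting	560	432	128	2
LCK	temporary	4	3	1	3
LCK	persisting	1187	899	288	3
MAF	temporary	4	3	1	3
MAF	persisting	594	450	144	3
NFAT	temporary	9	3	6	5
NFAT	persisting	604	452	152	5
NFKB	temporary	4	3	1	3
NFKB	persisting	594	450	144	3
NIK	temporary	4	3	1	3
NIK	persisting	1186	898	288	3
PI3K	temporary	4	3	1	3
PI3K	persisting	1186	898	288	3
PLCPG	temporary	4	3	1	3
PLCPG	persisting	596	452	144	3
SHP1	temporary	4	3	1	3
SHP1	persisting	594	450	144	3
SLP76	temporary	4	3	1	3
SLP76	persisting	594	450	144	3
SOCS1	temporary	8	5	3	3
SOCS1	persisting	978	594	384	3
STAT1	temporary	7	3	4	6
STAT1	persisting	1154	482	672	7
STAT4	temporary	4	3	1	3
STAT4	persisting	612	452	160	3
STAT6	temporary	6	3	3	3
STAT6	persisting	1664	1088	576	3
TBET	temporary	7	3	4	6
TBET	persisting	358	322	36	6
VAV1	temporary	4	3	1	3
VAV1	persisting	595	451	144	3
ZAP70	temporary	4	3	1	3
ZAP70	persisting	1186	898	288	3
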