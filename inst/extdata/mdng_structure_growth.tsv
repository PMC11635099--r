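# Structural features and joint-growth ranks of the 16 Mdng ORFs.
# length_aa = protein length; ids = average intrinsic disorder score (flDPnn,
# ingested, not computed); foldability = printed label (low: IDS > 0.4, high:
# IDS < 0.1, intermediate otherwise); growth_rank = rank in the joint growth
# experiment (1 = largest relative increase; NA = clone failed to grow).
# Values transcribed from the published summary table of the source study.
mdng	length_aa	ids	foldability	growth_rank
Mdng1	147	0.51	low	2
Mdng2	167	0.48	low	NA
Mdng3	157	0.08	high	5
Mdng4	122	0.06	high	4
Mdng5	111	0.43	low	7
Mdng6	48	0.50	low	10
Mdng7	143	0.19	intermediate	NA
Mdng9	133	0.23	intermediate	6
Mdng10	155	0.17	intermediate	11
Mdng11	91	0.06	high	12
Mdng12	155	0.24	intermediate	9
Mdng13	101	0.11	intermediate	14
Mdng14	101	0.63	low	13
Mdng15	102	0.28	intermediate	1
Mdng16	70	0.18	intermediate	3
Mdng21	115	0.09	high	8
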