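# Per-gene summary of the 16 mouse de novo gene (Mdng) expression experiments
# in human cells. expression = Mdng transcript level normalized to the
# hygromycin transcript of the same construct; n_de = number of host genes
# with |fold change| > 2 and adjusted p < 0.05; n_go = GO terms with p < 1e-3;
# top_go = top enriched GO term (pass-through annotation). Values transcribed
# from the published summary table of the source study; ingested, not
# computed by this package.
mdng	expression	n_de	n_go	top_go
Mdng1	0.94	300	4	GO:0061792 secretory granule maturation
Mdng2	0.36	520	31	GO:0043269 regulation of ion transport
Mdng3	0.39	1044	25	GO:0031620 regulation of fever generation
Mdng4	0.04	77	1	GO:0010984 regulation of lipoprotein particle clearance
Mdng5	0.25	266	14	GO:0007155 cell adhesion
Mdng6	0.15	126	14	GO:0007155 cell adhesion
Mdng7	0.52	35	0	none
Mdng9	0.16	188	41	GO:0003308 negative regulation of Wnt signaling pathway involved in heart development
Mdng10	0.35	108	4	GO:0006700 C21-steroid hormone biosynthetic process
Mdng11	0.02	405	55	GO:0007156 homophilic cell adhesion via plasma membrane adhesion molecules
Mdng12	0.25	118	15	GO:0042662 negative regulation of mesodermal cell fate specification
Mdng13	0.07	1171	101	GO:0030198 extracellular matrix organization
Mdng14	0.17	744	37	GO:0071805 potassium ion transmembrane transport
Mdng15	0.63	393	23	GO:0006873 cellular ion homeostasis
Mdng16	0.15	2392	4	GO:0006700 C21-steroid hormone biosynthetic process
Mdng21	0.07	1165	6	GO:0009097 isoleucine biosynthetic process
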