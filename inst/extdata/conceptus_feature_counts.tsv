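contrast	treatment	region	total	cpgIsland	geneBody	geneBodyUp	geneBodyDown
SOV_ED	SOV	ED	4	0	2	0	2
SOV_TE	SOV	TE	1452	18	432	393	39
SOV_TP	SOV	TP	971	7	309	132	177
IVP_ED	IVP	ED	35	0	11	0	11
IVP_TE	IVP	TE	289	3	78	35	43
IVP_TP	IVP	TP	389	8	136	85	51
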