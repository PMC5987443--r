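region	treatment	up	down	total
ED	SOV	1	3	4
ED	IVP	6	29	35
TE	SOV	1316	136	1452
TE	IVP	164	125	289
TP	SOV	397	574	971
TP	IVP	243	146	389
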