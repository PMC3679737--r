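primer	motif	orientation	sequence
15912	GGVGKTT, Kinase-1a	forward	GGTGGGGTTGGGAAGACAACG
15914	GGVGKTT, Kinase-1a	forward	GGIGGIGTIGGIAAIACIAC
16410	GGLGKTT, Kinase-1a	forward	GGIGGIYTIGGIAARACIAC
16403	GGMGKTT, Kinase-1a	forward	GGIGGIATIGGIAAAACIAC
16409	GGSGKTT, Kinase-1a	forward	GGIGGIWSIGGIAARACIAC
PLP	GG(G/O/M)GKTT, Kinase-1a	forward	GGIGGIRTIGGIAARACIAC
310	VLDDVW, Kinase-2	reverse	CCAIACRTCRTCNARNAC
antiK2	VLDDVW, Kinase-2	reverse	CCANACRTCRTCIARIAC
antiHD1	CKGLPL, HD	reverse	ARNGGIARICCYTTRCA
17609	FLDIACF, NBS-VI	reverse	RAARCAIGCSATRTCIARRAA
28107	FLHIACF, NBS-IX	reverse	RAARCAIGCDATRTGIARRAA
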