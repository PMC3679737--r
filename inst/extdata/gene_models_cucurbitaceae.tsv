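model_id	exon_lengths_aa	intron_phases	provenance
T1-A	180,290,160,210	0,0,1	four-exon deletion derivative of T1-B (exon 5 missing); exon lengths synthetic stand-in
T1-B	180,290,160,210,120	0,0,1,2	five-exon ancestral TIR model; exon lengths synthetic stand-in
T1-C	180,290,160,210,120,90	0,0,1,2,0	T1-B plus a sixth exon of foreign coding origin; exon lengths synthetic stand-in
T2	180,290,160,210	0,0,1	TIR model, structure identical to T1-A; exon lengths synthetic stand-in
T3	180,290,160,210	0,0,1	TIR model, structure identical to T1-A; exon lengths synthetic stand-in
T4	180,290,160,210	0,0,1	TIR model, structure identical to T1-A; exon lengths synthetic stand-in
T5	180,290,160,210	0,0,1	TIR model, structure identical to T1-A; exon lengths synthetic stand-in
T6	180,290,160,210	0,0,1	TIR model, structure identical to T1-A; exon lengths synthetic stand-in
T7	180,290,160,210	0,0,1	TIR model, structure identical to T1-A; exon lengths synthetic stand-in
N1	920		single-exon non-TIR model; synthetic stand-in
N2	870		single-exon non-TIR model; synthetic stand-in
N3	450,430	0	non-TIR model; synthetic stand-in
N4	1010		single-exon non-TIR model; synthetic stand-in
N5	300,420,310	1,2	non-TIR model; synthetic stand-in
N6	520,380	2	non-TIR model; synthetic stand-in
N7	880		single-exon non-TIR model; synthetic stand-in
N8	250,310,280,160	0,1,0	non-TIR model; synthetic stand-in
N9	610,290	1	non-TIR model; synthetic stand-in
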