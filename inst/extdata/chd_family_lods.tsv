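family	heart_defect	lod_15q26.3	lod_18q21.2
1	VSD	0.615	0.632
2	TOF,TGV	0.324	0.299
3	TOF	0.545	0.602
4	ASD	1.670	1.297
5	VSD,DORV	-0.307	0.602
6	ASD	0.681	0.496
All	VSD,TOF,TGV,ASD,DORV	3.529	3.929
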