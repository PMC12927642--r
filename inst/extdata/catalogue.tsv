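class_id	display_name	pathway_roles	reference_ids
3.7.1.1	oxaloacetate acetylhydrolase	biosynthesis	ref_3.7.1.1_1
1.2.3.5	glyoxylate oxidase	biosynthesis;other	ref_1.2.3.5_1
2.8.3.2	oxalate CoA-transferase	other	ref_2.8.3.2_1
2.8.3.19	succinyl-CoA:oxalate CoA-transferase	other	ref_2.8.3.19_1
4.1.1.8	oxalyl-CoA decarboxylase (Oxc)	biomineralization	ref_4.1.1.8_1;ref_4.1.1.8_2
2.8.3.16	formyl-CoA transferase (Frc)	biomineralization	ref_2.8.3.16_1
7.1.1.1	formate dehydrogenase (NAD+)	other	ref_7.1.1.1_1
1.2.1.17	oxalyl-CoA reductase	assimilation	ref_1.2.1.17_1
2.1.2.1	serine hydroxymethyltransferase	assimilation	ref_2.1.2.1_1
2.6.1.45	serine-glyoxylate transaminase	assimilation	ref_2.6.1.45_1
4.1.1.47	glyoxylate carboligase (Gcl)	assimilation	ref_4.1.1.47_1;ref_4.1.1.47_2
1.1.1.60	tartronate semialdehyde reductase	assimilation	ref_1.1.1.60_1
2.7.1.31	glycerate 3-kinase	assimilation	ref_2.7.1.31_1
1.1.1.29	hydroxypyruvate reductase	assimilation	ref_1.1.1.29_1
4.1.1.2	oxalate decarboxylase	other	ref_4.1.1.2_1
1.2.3.4	oxalate oxidase	other	ref_1.2.3.4_1
4.1.1.20	diaminopimelate decarboxylase	other	ref_4.1.1.20_1
OxlT	oxalate:formate antiporter	biomineralization	ref_OxlT_1
6.2.1.8	oxalate--CoA ligase	other	ref_6.2.1.8_1
1.1.1.26	glyoxylate reductase	assimilation;other	ref_1.1.1.26_1
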