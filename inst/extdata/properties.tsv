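designation	code	axis	approximate
Area	42798000	qualifier value	FALSE
Class	277046005	attribute	FALSE
Colour	263714004	qualifier value	FALSE
Consistency	246191002	attribute	FALSE
CytologicAtypia	50673007	morphologic abnormality	FALSE
Diameter	81827009	qualifier value	FALSE
Distance	246132006	qualifier value	FALSE
General clinical stage for disease AND/OR neoplasm	106240007	qualifier value	FALSE
Grade	103421006	attribute	FALSE
Involvement	278112009	attribute	FALSE
MarkerStatus	246110002	attribute	FALSE
Measurement	122869004	procedure	FALSE
NeighborhoodRelationship	408739003	attribute	TRUE
Number	410680006	attribute	FALSE
Pattern	255711007	attribute	FALSE
Regularity	246202005	attribute	FALSE
ResidualDisease	65320000	qualifier value	FALSE
Shape	300842002	attribute	FALSE
Size	246115007	attribute	FALSE
SpecificDeposits	46595003	morphologic abnormality	FALSE
(Treatment)Effect	253861007	qualifier value	TRUE
Weight	272102008	qualifier value	FALSE
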