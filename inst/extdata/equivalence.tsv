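oid	oid_example	pattern	element	family	target	property	qualifiers	method	note
1.3.6.1.4.1.19376.1.8.1.4.54	TRUE	Cytological type	Class	staging_grading_classification	Cell	Class			
1.3.6.1.4.1.19376.1.8.1.4.164	TRUE	Lesion size, largest dimension	Diameter	core_generic	Lesion	Diameter	Largest	ObservedByMicroscopicInvestigation	worked example elsewhere cites OID 1.3.6.1.4.1.49376.1.8.1.4.442 (branch 49376 vs 19376, likely typographic); both recorded, neither corrected
1.3.6.1.4.1.19376.1.8.1.4.146	FALSE	Distance of lesion from closest uninvolved margin	Distance	core_generic	Lesion	Distance	Nearest	ObservedByMicroscopicInvestigation	
1.3.6.1.4.1.19376.1.8.1.4.162	FALSE	Treatment effect	Treatment Effect	core_generic	Lesion	(Treatment)Effect			
1.3.6.1.4.1.19376.1.8.1.4.149	FALSE	Extent	Extent	core_generic	Lesion	Size			
1.3.6.1.4.1.19376.1.8.1.4.143	FALSE	Lesion focality	Focality	core_generic	Lesion	Pattern	Focality		also a qualifier row in the qualifier table; kept as equivalence-row alias
1.3.6.1.4.1.19376.1.8.1.4.151	TRUE	Histological grade (WHO)	Grade	staging_grading_classification	Lesion	Grade			
1.3.6.1.4.1.19376.1.8.1.4.168	FALSE	Macroscopic type	Growth pattern	core_generic	Lesion	Pattern			
1.3.6.1.4.1.19376.1.8.1.4.174	FALSE	Specimen integrity	Integrity	core_generic	Specimen	Regularity			
1.3.6.1.4.1.19376.1.8.1.4.141	TRUE	Margins involvement	Involvement	core_generic	Margin	Involvement		ObservedByMicroscopicInvestigation	
1.3.6.1.4.1.19376.1.8.1.4.439	TRUE	Estrogen receptor	Marker	marker	Tissue	MarkerStatus			
1.3.6.1.4.1.19376.1.8.1.4.318	TRUE	Lesion ulceration	Neighborhood relationship	core_generic	Lesion	NeighborhoodRelationship			
1.3.6.1.4.1.19376.1.8.1.4.156	TRUE	Number of lymph nodes involved	Number	core_generic	Organ	Number		ObservedByMicroscopicInvestigation	
1.3.6.1.4.1.19376.1.8.1.4.148	TRUE	Lymph node sampling	Procedure	procedure	Specimen	Measurement			procedures remain a classification category only
1.3.6.1.4.1.19376.1.8.1.4.169	TRUE	Lesion site	Site	core_generic	Lesion	Class			
1.3.6.1.4.1.19376.1.8.1.4.161	TRUE	pT	Stage	staging_grading_classification	Disease	General clinical stage for disease AND/OR neoplasm			
1.3.6.1.4.1.19376.1.8.1.4.160	FALSE	Specimen weight	Weight	core_generic	Specimen	Weight			
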