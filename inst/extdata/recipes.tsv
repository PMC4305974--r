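designation	family	pattern	target	property	qualifiers	method	table1_element	value_set	contexts
Diameter	core_generic	Lesion size, largest dimension	Lesion	Diameter	Largest	ObservedByMicroscopicInvestigation	Diameter		20
Distance	core_generic	Distance of lesion from closest uninvolved margin	Lesion	Distance	Nearest	ObservedByMicroscopicInvestigation	Distance		20
Extent	core_generic	Extent	Lesion	Size		ObservedByMicroscopicInvestigation	Extent	limited|extensive|cannot be determined	20
Focality	core_generic	Lesion focality	Lesion	Pattern	Focality	ObservedByMacroscopicInvestigation	Focality	unifocal|multifocal	20
Growth pattern	core_generic	Macroscopic type	Lesion	Pattern		ObservedByMacroscopicInvestigation	Growth pattern	exophytic|ulcerating|infiltrative|diffuse	20
Integrity	core_generic	Specimen integrity	Specimen	Regularity		ObservedByMacroscopicInvestigation	Integrity	intact|fragmented	20
Involvement	core_generic	Margins involvement	Margin	Involvement		ObservedByMicroscopicInvestigation	Involvement	involved|not involved|cannot be assessed	20
Number	core_generic	Number of lymph nodes involved	Organ	Number		ObservedByMicroscopicInvestigation	Number		20
Weight	core_generic	Specimen weight	Specimen	Weight		ObservedByMacroscopicInvestigation	Weight		20
Stage pT	staging_grading_classification	pT	Disease	General clinical stage for disease AND/OR neoplasm			Stage	pT0|pT1|pT2|pT3|pT4|pTX	8
Stage pN	staging_grading_classification	pN	Disease	General clinical stage for disease AND/OR neoplasm			Stage	pN0|pN1|pN2|pN3|pNX	8
Stage pM	staging_grading_classification	pM	Disease	General clinical stage for disease AND/OR neoplasm			Stage	pM0|pM1|pMX	8
Stage ypT	staging_grading_classification	ypT	Disease	General clinical stage for disease AND/OR neoplasm			Stage	ypT0|ypT1|ypT2|ypT3|ypT4|ypTX	8
Stage ypN	staging_grading_classification	ypN	Disease	General clinical stage for disease AND/OR neoplasm			Stage	ypN0|ypN1|ypN2|ypNX	8
Stage ypM	staging_grading_classification	ypM	Disease	General clinical stage for disease AND/OR neoplasm			Stage	ypM0|ypM1|ypMX	8
Pathologic stage group	staging_grading_classification	Pathologic stage group	Disease	General clinical stage for disease AND/OR neoplasm			Stage	Stage 0|Stage I|Stage II|Stage III|Stage IV	8
Clinical stage group	staging_grading_classification	Clinical stage group	Disease	General clinical stage for disease AND/OR neoplasm			Stage	Stage 0|Stage I|Stage II|Stage III|Stage IV	8
Residual tumor classification	staging_grading_classification	Residual tumor classification	Disease	ResidualDisease			Stage	R0|R1|R2|RX	8
FIGO stage	staging_grading_classification	FIGO stage	Disease	General clinical stage for disease AND/OR neoplasm			Stage	FIGO I|FIGO II|FIGO III|FIGO IV	8
Ann Arbor stage	staging_grading_classification	Ann Arbor stage	Disease	General clinical stage for disease AND/OR neoplasm			Stage	Stage I|Stage II|Stage III|Stage IV	8
Dukes stage	staging_grading_classification	Dukes stage	Disease	General clinical stage for disease AND/OR neoplasm			Stage	Dukes A|Dukes B|Dukes C|Dukes D	8
Histological grade (WHO)	staging_grading_classification	Histological grade (WHO)	Lesion	Grade		ObservedByMicroscopicInvestigation	Grade	G1|G2|G3|G4|GX	8
Nuclear grade	staging_grading_classification	Nuclear grade	Lesion	Grade		ObservedByMicroscopicInvestigation	Grade	low|intermediate|high	8
Nottingham histologic score	staging_grading_classification	Nottingham histologic score	Lesion	Grade		ObservedByMicroscopicInvestigation	Grade	score 3-5|score 6-7|score 8-9	8
Gleason score	staging_grading_classification	Gleason score	Lesion	Grade		ObservedByMicroscopicInvestigation	Grade	6|7|8|9|10	8
Fuhrman grade	staging_grading_classification	Fuhrman grade	Lesion	Grade		ObservedByMicroscopicInvestigation	Grade	1|2|3|4	8
ISUP grade group	staging_grading_classification	ISUP grade group	Lesion	Grade		ObservedByMicroscopicInvestigation	Grade	1|2|3|4|5	8
Tubule formation score	staging_grading_classification	Tubule formation score	Lesion	Grade		ObservedByMicroscopicInvestigation	Grade	1|2|3	8
Mitotic count score	staging_grading_classification	Mitotic count score	Lesion	Grade		ObservedByMicroscopicInvestigation	Grade	1|2|3	8
ICD-O morphology code	staging_grading_classification	ICD-O morphology code	Disease	Class			Class	8140/3|8500/2|8070/3|8720/3	8
ICD-O topography code	staging_grading_classification	ICD-O topography code	Disease	Class			Class	C50.1|C50.4|C18.7|C61.9	8
Cytological type	staging_grading_classification	Cytological type	Cell	Class			Class	squamous|glandular|other	8
Histological type (WHO classification)	staging_grading_classification	Histological type (WHO classification)	Disease	Class			Class	adenocarcinoma|squamous cell carcinoma|other	8
Bethesda category	staging_grading_classification	Bethesda category	Disease	Class			Class	I|II|III|IV|V|VI	8
BI-RADS category	staging_grading_classification	BI-RADS category	Disease	Class			Class	0|1|2|3|4|5|6	8
Lauren classification	staging_grading_classification	Lauren classification	Disease	Class			Class	intestinal|diffuse|mixed	8
WHO/ISUP classification	staging_grading_classification	WHO/ISUP classification	Disease	Class			Class	low grade|high grade	8
Marker Estrogen receptor	marker	Estrogen receptor	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker Progesterone receptor	marker	Progesterone receptor	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker HER2	marker	HER2	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker Ki-67	marker	Ki-67	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker p53	marker	p53	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker CD3	marker	CD3	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker CD20	marker	CD20	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker CD117	marker	CD117	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker S100 protein	marker	S100 protein	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker Cytokeratin 7	marker	Cytokeratin 7	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker Cytokeratin 20	marker	Cytokeratin 20	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker TTF-1	marker	TTF-1	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker PSA	marker	PSA	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker Synaptophysin	marker	Synaptophysin	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Marker Chromogranin A	marker	Chromogranin A	Tissue	MarkerStatus		ObservedByMicroscopicInvestigation	Marker	positive|negative|equivocal	3
Treatment Effect	unclassified_generic	Treatment effect	Lesion	(Treatment)Effect		ObservedByMicroscopicInvestigation	Treatment Effect	no effect|partial response|complete response|not applicable	1
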