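designation	code	axis	approximate
Cell	362837007	cell structure	FALSE
Disease	64572001	disorder	FALSE
Lesion	49755003	morphologic abnormality	FALSE
Margin	82868003	body structure	FALSE
Mitotic nucleus	49307000	cell structure	FALSE
Nucleolus	15982001	cell structure	FALSE
Nucleus	84640000	cell structure	FALSE
Organ	272625005	body structure	FALSE
Specimen	123038009	specimen	FALSE
Tissue	85756007	body structure	FALSE
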