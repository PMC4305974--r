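designation	code	axis	approximate
Laterality	272741003	attribute	FALSE
Focality			FALSE
Invasiveness	10179008	qualifier value	FALSE
ScaleType	370132008	attribute	FALSE
normalStructure	361083003	body structure	FALSE
abnormalStructure	49755003	morphologic abnormality	FALSE
specialAttributes			FALSE
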