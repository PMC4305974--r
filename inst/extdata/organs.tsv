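organ
Breast
Prostate
Lung
Colon
Rectum
Stomach
Esophagus
Liver
Pancreas
Kidney
Bladder
Uterus
Cervix
Ovary
Thyroid
Skin
Larynx
Testis
Brain
Lymph node
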