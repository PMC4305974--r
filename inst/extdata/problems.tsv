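token	problem
In situ neoplasm	non-invasive tumor
Non-invasive neoplasm	non-invasive tumor
Invasive neoplasm	invasive tumor
Invasive carcinoma	invasive tumor
Non-neoplastic disease	non-neoplastic problem
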