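{
  "seed": 0,
  "oid_branch": "2.25.42424242.4",
  "problems": ["Invasive neoplasm", "In situ neoplasm"],
  "contexts_per_family": {
    "core_generic": 20,
    "staging_grading_classification": 8,
    "marker": 3,
    "unclassified_generic": 1
  },
  "specific_elements": [
    "Peculiar stromal reaction",
    "Crypt abscess density",
    "Desmoplastic response intensity",
    "Paneth cell metaplasia presence",
    "Serrated architecture proportion",
    "Follicular dendritic meshwork disruption"
  ],
  "specific_occurrences": [3, 3, 3, 3, 3, 2],
  "specific_value_set": ["absent", "present", "marked"],
  "procedure_names": [
    "Specimen photography",
    "Gross sectioning",
    "Frozen section preparation",
    "Tissue fixation",
    "Paraffin embedding",
    "Routine H and E staining",
    "Immunohistochemical staining run",
    "Decalcification",
    "Specimen radiography",
    "Whole slide scanning",
    "Image annotation",
    "Macrodissection",
    "Microdissection",
    "Cytospin preparation",
    "Cell block preparation",
    "Smear preparation",
    "Special staining run",
    "Molecular testing run",
    "Specimen accessioning",
    "Slide archiving",
    "Specimen disposal"
  ]
}
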