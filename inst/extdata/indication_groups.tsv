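group	pattern
unknown or missing	unknown indication|product used for unknown
melanoma	melanoma
lung cancer	lung|bronch|small cell
mesothelioma	mesothelioma
hematological cancer and lymphoma	lymphoma|leukaemia|leukemia|myeloma|hodgkin|haematolog|hematolog|myelodysplastic
gastrointestinal cancer	gastric|gastro|colon|colorect|rectal|oesophag|esophag|pancrea|hepatocellular|hepatic|liver|biliary|bile|cholangio|anal cancer
head and neck cancer	head and neck|oral|laryn|pharyn|tongue|thyroid
breast cancer	breast
tumors of female reproductive organs	ovar|cervi|uterine|endometri|fallopian|vulv|vagin
tumors of urinary system	renal|kidney|bladder|urothelial|urinary
non-specified malignant neoplasm	malignant neoplasm|neoplasm malignant|metastas|metastatic neoplasm
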