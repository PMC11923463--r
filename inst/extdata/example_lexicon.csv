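"surface","canonical","class","atc"
"ivermectin","ivermectin","drug","P"
"ivm","ivermectin","drug","P"
"hydroxychloroquine","hydroxychloroquine","drug","P"
"hcq","hydroxychloroquine","drug","P"
"plaquenil","hydroxychloroquine","drug","P"
"remdesivir","remdesivir","drug","J"
"zinc","zinc","drug","A"
"vitamin d","vitamin d","drug","A"
"vit d","vitamin d","drug","A"
"azithromycin","azithromycin","drug","J"
"zpack","azithromycin","drug","J"
"fever","fever","symptom",NA
"cough","cough","symptom",NA
"headache","headache","symptom",NA
"nausea","nausea","symptom",NA
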