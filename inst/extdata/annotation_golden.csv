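drug_id,text,expected
D01,Take with food to reduce nausea.,1
D02,Avoid alcohol.,0
D03,Take with or without food.,2
D04,Take at the same time every day.,ignored
D05,Take with food.,1
D06,Take after meals.,1
D07,Take after a meal.,1
D08,Food reduces irritation.,1
D09,Food decreases the risk of gastrointestinal side effects.,1
D10,Take on an empty stomach.,0
D11,Take before a meal.,0
D12,Take separately from meals.,0
D13,Avoid grapefruit juice.,0
D14,Take consistently with regard to food.,2
D15,Food increases the extent of absorption.,1
D16,Food increases bioavailability.,1
D17,Food increases peak concentrations.,1
D18,Food decreases time to peak concentrations.,1
D19,Food reduces the extent of absorption and at least one adverse effect or toxicity for human health has been described.,0
D20,Food decreases bioavailability and increases the risk of toxicity.,0
D21,Food reduces bioavailability and may cause harm to the patient.,0
D22,Food delays gastric emptying.,2
D23,Food increases the extent of absorption and no adverse effect or toxicity has been observed.,1
D24,Administer with a full glass of water.,2
D25,Take at the same time every day.,0
D25,Avoid alcohol.,0
D26,Take with food.,0
D26,Avoid taking this medication with grapefruit juice.,0
D27,Take with or without food.,1
D27,Take with food.,1
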