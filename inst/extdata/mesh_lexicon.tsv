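Liposarcoma	Myxoid
CDK4 Amplification	Cyclin-Dependent Kinase 4
CDK4 Amplification	Proto-Oncogene Proteins c-mdm2
38-year-old	Middle Aged
38-year-old	Adult
38-year-old	Male
38-year-old	Human
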