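patient_id,variant_combo,drug,dose_nM,activity,untreated_activity
3,FLT3 M665T,sorafenib,1,92,95
3,FLT3 M665T,sorafenib,4.31736,85,95
3,FLT3 M665T,sorafenib,18.6396,60,95
3,FLT3 M665T,sorafenib,80.4738,35,95
3,FLT3 M665T,sorafenib,347.435,18,95
3,FLT3 M665T,sorafenib,1500,6,95
4,KIT D572G,imatinib,2.5,78,80
4,KIT D572G,imatinib,9.95268,70,80
4,KIT D572G,imatinib,39.6223,55,80
4,KIT D572G,imatinib,157.739,30,80
4,KIT D572G,imatinib,627.972,15,80
4,KIT D572G,imatinib,2500,5,80
5,BRAF V600E,vemurafenib,2.5,98,100
5,BRAF V600E,vemurafenib,9.95268,90,100
5,BRAF V600E,vemurafenib,39.6223,72,100
5,BRAF V600E,vemurafenib,157.739,45,100
5,BRAF V600E,vemurafenib,627.972,22,100
5,BRAF V600E,vemurafenib,2500,9,100
8,ERBB2 T862A + KRAS G12S,lapatinib,2.5,88,90
8,ERBB2 T862A + KRAS G12S,lapatinib,9.95268,86,90
8,ERBB2 T862A + KRAS G12S,lapatinib,39.6223,83,90
8,ERBB2 T862A + KRAS G12S,lapatinib,157.739,80,90
8,ERBB2 T862A + KRAS G12S,lapatinib,627.972,76,90
8,ERBB2 T862A + KRAS G12S,lapatinib,2500,72,90
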