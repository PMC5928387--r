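patient_id,cancer_type,mta,treatment_basis,basis_alteration,gene,protein_change,variant_class,reporter_pathway,active,pfs_months,event
1,Head & Neck cancer,erlotinib,amplification,EGFR amplification,MET,R988C,VUS,MAPK/ERK,TRUE,3.7,TRUE
2,Head & Neck cancer,sorafenib,assayed_variant,,PIK3CA,E545K,known,PI3K/AKT,TRUE,1.3,TRUE
2,Head & Neck cancer,sorafenib,assayed_variant,,PDGFRA,L655W,VUS,MAPK/ERK,FALSE,1.3,TRUE
3,Lung cancer,sorafenib,assayed_variant,,FLT3,M665T,VUS,MAPK/ERK,TRUE,5.9,TRUE
4,Lung cancer,imatinib,assayed_variant,,KIT,D572G,VUS,MAPK/ERK,TRUE,8.4,TRUE
5,Colorectal cancer,vemurafenib,assayed_variant,,BRAF,V600E,known,MAPK/ERK,TRUE,5.6,TRUE
6,Ovarian cancer,imatinib,assayed_variant,,KIT,V852I,VUS,MAPK/ERK,FALSE,3.7,TRUE
7,Hepatocellular carcinoma,imatinib,assayed_variant,,KIT,M722V,VUS,MAPK/ERK,FALSE,1.5,TRUE
8,Neuroendocrine cancer,lapatinib + trastuzumab,assayed_variant,,ERBB2,T862A,known,MAPK/ERK,TRUE,1.1,TRUE
8,Neuroendocrine cancer,lapatinib + trastuzumab,assayed_variant,,KRAS,G12S,known,MAPK/ERK,TRUE,1.1,TRUE
9,Lung cancer,lapatinib + trastuzumab,amplification,ERBB2 amplification,EGFR,E746_T751>A,known,MAPK/ERK,TRUE,2.0,TRUE
10,Colorectal cancer,lapatinib + trastuzumab,assayed_variant,,ERBB2,S792F,VUS,MAPK/ERK,FALSE,1.9,TRUE
10,Colorectal cancer,lapatinib + trastuzumab,assayed_variant,,KRAS,G12D,known,MAPK/ERK,TRUE,1.9,TRUE
11,Colorectal cancer,sorafenib,amplification,PDGFRA amplification,PIK3CA,E545K,known,PI3K/AKT,TRUE,2.3,TRUE
12,Melanoma,imatinib,assayed_variant,,KIT,P838S,VUS,MAPK/ERK,FALSE,1.6,TRUE
12,Melanoma,imatinib,assayed_variant,,NRAS,Q61L,known,MAPK/ERK,TRUE,1.6,TRUE
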