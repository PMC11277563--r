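mirna_id	direction	source	reference
hsa-miR-34a-5p	down	tissue	oscc-tissue-majority
hsa-miR-34a-5p	down	saliva	oscc-saliva-majority
hsa-miR-34a-5p	up	saliva	oscc-saliva-minority
hsa-miR-124-3p	down	tissue	oscc-tissue
hsa-miR-124-3p	down	saliva	oscc-saliva
hsa-miR-125b-5p	down	tissue	oscc-tissue
hsa-miR-1-3p	down	tissue	oscc-tissue
hsa-miR-147a	down	saliva	oscc-saliva
hsa-miR-155-5p	up	tissue	oscc-tissue
hsa-miR-155-5p	up	saliva	oscc-saliva
hsa-miR-423-3p	up	tissue	oscc-tissue
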