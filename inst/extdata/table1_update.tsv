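mirna_id	direction	source	reference
miR-1307-5p	up	saliva_exosome	update-2024-r26
miR-193b-3p	up	saliva	update-2024-r26
miR-19a-3p	up	tissue	update-2024-r28
miR-200c-3p	up	tissue	update-2024-r6
miR-200c-3p	up	cell_line	update-2024-r6
miR-23a-3p	up	tissue	update-2024-r6
miR-23a-3p	up	cell_line	update-2024-r6
miR-345-5p	up	tissue	update-2024-r26
miR-345-5p	up	saliva	update-2024-r27
miR-378a	up	tissue	update-2024-r6
miR-378a	up	cell_line	update-2024-r6
let-7g-5p	down	tissue	update-2024-r28
miR-133b	down	tissue	update-2024-r27
miR-140-5p	down	saliva_exosome	update-2024-r26
miR-143-5p	down	saliva_exosome	update-2024-r26
miR-15a-5p	down	saliva	update-2024-r26
miR-16-1-3p	down	saliva	update-2024-r26
miR-30c-5p	down	saliva	update-2024-r26
miR-363-3p	down	tissue	update-2024-r28
miR-3928	down	saliva	update-2024-r26
miR-424-3p	down	saliva	update-2024-r26
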