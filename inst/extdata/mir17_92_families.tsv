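family_id	motif7	motif8	members
miR-17-5p/20-5p/106-5p	AAAGTGC	TAAAGTGC	hsa-miR-17-5p;hsa-miR-20a-5p;hsa-miR-106a-5p;hsa-miR-106b-5p;hsa-miR-20b-5p
miR-18-5p	AGTGCAT	AAGTGCAT	hsa-miR-18a-5p;hsa-miR-18b-5p
miR-19-3p	GTGCAAA	TGTGCAAA	hsa-miR-19a-3p;hsa-miR-19b-3p
miR-92-3p	ATTGCAC	TATTGCAC	hsa-miR-92a-3p;hsa-miR-92b-3p
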