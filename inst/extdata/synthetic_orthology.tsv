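rat_id	human_id
rno-let-7c-5p	hsa-let-7c-5p
rno-miR-132-3p	hsa-miR-132-3p
rno-miR-155-5p	hsa-miR-155-5p
rno-miR-665	hsa-miR-665
rno-miR-130b-3p	hsa-miR-130b-3p
rno-miR-223-3p	hsa-miR-223-3p
rno-miR-496-3p	hsa-miR-496-3p
rno-miR-21-3p	hsa-miR-21-3p
rno-miR-361-3p	hsa-miR-361-3p
rno-miR-3557-5p	NA
rno-miR-3065-3p	NA
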