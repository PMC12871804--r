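# Orthologous-element character states per species: presence of the
# intron-embedded FLAM-C Alu element and the number of AATAAA hexamers at
# its 3' tail. "lost" marks species where deletion breakpoints show the
# element was ancestrally present and secondarily removed; pas_count is NA
# wherever the element (and hence the region) is missing.
tip	presence	pas_count
human	present	3
neanderthal	present	3
chimp	present	1
bonobo	present	1
gorilla	present	1
orangutan	present	1
siamang	present	2
hoolock	present	2
macaque	present	1
colobus	present	0
langur	present	0
marmoset	lost	NA
tarsier	absent	NA
lemur	absent	NA
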