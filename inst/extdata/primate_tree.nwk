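(lemur:74,(tarsier:65,(marmoset:43,((macaque:18,(colobus:10,langur:10):8):11,((siamang:8,hoolock:8):12,(orangutan:16,(gorilla:9,((chimp:2.5,bonobo:2.5):3.5,(human:0.5,neanderthal:0.45):5.5):3):7):4):9):14):22):9);
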