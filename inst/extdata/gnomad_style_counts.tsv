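population	hom_alt_individuals	total_alleles
overall	2812	280488
latino	979	35218
african	16	24528
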