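gene	coding_length_bp	chrom	start	end
TP53	1182	17	7571720	7590868
DNMT3A	2739	2	25455845	25565459
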