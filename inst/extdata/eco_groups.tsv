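column	value	pool	label
Domain	Archaea		Archaea
Order	Chloroplast	SSU16S	Chloroplast 16S
Class	Cyanobacteria	SSU16S	Cyanobacteria
Class	Alphaproteobacteria	SSU16S	Alphaproteobacteria
Class	Gammaproteobacteria	SSU16S	Gammaproteobacteria
Phylum	Bacteroidota	SSU16S	Bacteroidota
Domain	Bacteria	SSU16S	Other Bacteria
		SSU18S	Eukaryote 18S
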