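# Variant sites (CDS offsets) of the four interval genes. The 318 bp site
# of Capana06g002969 converts the restorer-line stop codon TGA to TGG in
# the CMS line (stop loss / read-through); it is non-synonymous and
# eligible for concordance scoring.
gene	cds_offset	cms_allele	restorer_allele	consequence
Capana06g002965	129	A	C	MISSENSE
Capana06g002965	436	T	C	SYNONYMOUS
Capana06g002965	504	G	A	MISSENSE
Capana06g002967	935	G	A	MISSENSE
Capana06g002968	20	G	C	MISSENSE
Capana06g002968	467	T	G	MISSENSE
Capana06g002969	144	G	A	SYNONYMOUS
Capana06g002969	196	T	G	MISSENSE
Capana06g002969	318	G	A	STOP_LOSS
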