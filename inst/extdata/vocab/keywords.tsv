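# Keyword token lists (case-insensitive substring match).
# viral_function: products counted as viral replication/structure/function
#   and therefore excluded when calling auxiliary metabolic genes (AMGs).
# organelle: product/taxonomy tokens marking organellar (mitochondrial /
#   chloroplast) fragments mis-circularized from eukaryotic source DNA.
# Columns: type, token.
type	token
viral_function	capsid
viral_function	terminase
viral_function	portal
viral_function	tail
viral_function	baseplate
viral_function	virion
viral_function	phage head
viral_function	sheath
viral_function	tape measure
viral_function	holin
viral_function	lysin
viral_function	lysozyme
viral_function	integrase
viral_function	recombinase
viral_function	excisionase
viral_function	polymerase
viral_function	primase
viral_function	ssb
viral_function	phage
organelle	mitochondri
organelle	chloroplast
organelle	plastid
organelle	thylakoid
organelle	rubisco
organelle	Streptophyta
organelle	Chlorophyta
organelle	Bacillariophyta
organelle	Ascomycota
organelle	Basidiomycota
organelle	Metazoa
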