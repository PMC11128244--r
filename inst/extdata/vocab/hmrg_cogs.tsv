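# Heavy-metal-resistance-gene COGs curated for this package (in-package
# default list; best-effort curation keyed to commonly reported HMRG gene
# names, override via load_vocabulary(dir=...)).
# Columns: cog_id, gene_name, metals (comma-joined element symbols).
cog_id	gene_name	metals
COG2217	zntA	Zn,Cd,Pb
COG1249	merA	Hg
COG0789	merR	Hg,Zn,Cu
COG2608	copZ	Cu
COG2059	chrA	Cr
COG4275	chrB1	Cr
COG3696	cusA	Cu,Zn,Cd,Co,Ni
COG1276	pcoB	Cu
COG5569	cusF	Cu
COG1230	czcD	Zn,Co,Cd
COG0640	arsR	As
COG1393	arsC	As
COG1055	arsB	As
COG0798	acr3	As
COG0003	arsA	As
COG0861	terC	Te
COG0500	tehB	Te
COG2310	terD	Te
COG3853	telA	Te
COG2132	cueO	Cu
COG0598	corA	Co,Ni
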