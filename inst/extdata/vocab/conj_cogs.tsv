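# Conjugal-transfer-system COGs (type IV secretion, coupling and relaxase
# machinery of conjugative plasmids and ICEs); in-package default list.
# Columns: cog_id, gene_name.
cog_id	gene_name
COG3505	virD4
COG3451	virB4
COG3846	virB6
COG2948	virB10
COG3736	virB8
COG3843	virD2
COG3704	trbL
COG4959	traF
COG0433	traB
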