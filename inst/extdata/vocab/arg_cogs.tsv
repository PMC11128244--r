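# Antibiotic-resistance-gene COGs curated for this package (in-package
# default list; best-effort curation).
# Columns: cog_id, gene_name.
cog_id	gene_name
COG2367	ampC
COG1680	ampH
COG0841	acrB
COG1566	emrA
COG1670	aac
COG1181	vanA
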