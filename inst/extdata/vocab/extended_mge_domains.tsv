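# Extended-library domain ids (CDD/TIGRFAM/SMART/PGAP namespaces) used for
# the manual second-pass screen for mobility/replication domains on elements
# left unclassified by the Pfam screen. Best-effort in-package transcription;
# no authoritative published list exists for this screen.
# Columns: domain_id, note.
domain_id	note
TIGR01766	conjugative relaxase TraA
TIGR02249	integrase catalytic core
CD00338	ParB-like plasmid partition protein
CD03278	type IV secretion VirB4 ATPase
NF033077	MOB-family mobilization relaxase
NF012798	tyrosine-recombinase phage integrase
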