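# Mobile-genetic-element-associated Pfam domains; in-package default list.
# `replication` marks plasmid replication-initiation families.
# Columns: pfam_id, name, replication (yes/no).
pfam_id	name	replication
PF01051	Rep_3	yes
PF01446	Rep_1	yes
PF01719	Plasmid_Rep	yes
PF02486	Rep_trans	yes
PF03090	Replicase	yes
PF04796	RepL	yes
PF01076	Mob_Pre	no
PF03432	Relaxase	no
PF00589	Phage_integrase	no
PF00665	rve	no
PF01609	DDE_Tnp_1	no
PF13007	Tnp_IS66	no
PF05598	DUF772	no
PF01526	Tn3_DDE	no
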