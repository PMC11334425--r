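table	column	type	description
candidates	protein_id	string	Candidate flavinylation-substrate protein
candidates	family	string	Best-match domain family accession of the candidate
candidates	n_sites	integer	Number of [S/T]GA[S/T]-type motif sites in the protein
candidates	genome_id	string	Genome carrying the candidate
candidates	cluster_id	integer	Index of the anchor window the candidate was found in
candidates	anchor_gene_id	string	Anchor (apbE-family) gene of that window
candidates	multi_flavinylated	logical	TRUE when n_sites > 2
cluster_summary	cluster_id	integer	Cluster index (one row per anchor gene)
cluster_summary	genome_id	string	Genome of the anchor
cluster_summary	contig_id	string	Contig of the anchor
cluster_summary	anchor_gene_id	string	Anchor gene identifier
cluster_summary	anchor_protein_id	string	Anchor protein identifier
cluster_summary	n_members	integer	Genes in the window (<= 2k+1)
cluster_summary	window_k	integer	Window half-width in genes
cluster_summary	targets_present	string	Comma-separated target families found in the window
cluster_members	cluster_id	integer	Cluster index
cluster_members	genome_id	string	Genome of the window
cluster_members	contig_id	string	Contig of the window
cluster_members	anchor_gene_id	string	Anchor gene of the window
cluster_members	gene_id	string	Member gene
cluster_members	ordinal	integer	0-based gene ordinal along the contig
cluster_members	start	integer	1-based inclusive start coordinate
cluster_members	end	integer	1-based inclusive end coordinate
cluster_members	strand	string	Gene strand (+/-)
cluster_members	protein_id	string	Protein of the member gene (. if non-coding)
cluster_members	family	string	Best-match family of the member protein (NA if unannotated)
cluster_members	is_anchor	logical	TRUE for the anchor gene row
motif_sites	protein_id	string	Protein carrying the site (candidates only)
motif_sites	start	integer	1-based start of the motif match
motif_sites	matched	string	Matched residues
motif_sites	flavinylated_pos	integer	1-based position of the modified S/T
taxonomy	rank	string	Taxonomic rank of the summary (default phylum)
taxonomy	taxon	string	Taxon name from the GTDB lineage
taxonomy	n_genomes_with_feature	integer	Genomes in the taxon with >=1 candidate
taxonomy	n_genomes_total	integer	Genomes observed for the taxon
taxonomy	fraction	numeric	n_genomes_with_feature / n_genomes_total
colocalization_frequency	target_family	string	Target family accession
colocalization_frequency	n_anchors	integer	Number of anchor windows examined
colocalization_frequency	fraction	numeric	Fraction of anchor windows containing the target family
tm_segments	chain	string	Chain identifier
tm_segments	start	integer	First residue of the qualifying hydropathy-center run
tm_segments	end	integer	Last residue of the run
tm_segments	length	integer	Run length in residues
tm_segments	mean_hydropathy	numeric	Mean Kyte-Doolittle hydropathy over the segment residues
tm_segments	peak_window_mean	numeric	Maximum windowed-mean hydropathy inside the segment
tm_segments	structure_id	string	Source structure (file stem)
heme_pairs	chain_a	string	Chain of the first His
heme_pairs	resno_a	integer	Residue number of the first His
heme_pairs	atom_a	string	Coordinating atom used (NE2, ND1 fallback)
heme_pairs	chain_b	string	Chain of the second His
heme_pairs	resno_b	integer	Residue number of the second His
heme_pairs	atom_b	string	Coordinating atom used
heme_pairs	distance	numeric	Coordinating-atom distance in Angstrom
heme_pairs	same_chain	logical	TRUE for intra-chain pairs
heme_pairs	sequence_separation	integer	|resno_a - resno_b| for intra-chain pairs, NA across chains
heme_pairs	structure_id	string	Source structure (file stem)
pocket_distances	structure_id	string	Source structure (file stem)
pocket_distances	motif_resno	integer	Residue number of the motif S/T
pocket_distances	ligand	string	Ligand whose heavy atoms define the pocket centroid
pocket_distances	distance	numeric	Motif-hydroxyl-to-pocket-centroid distance in Angstrom
pocket_distances	proximal	logical	TRUE when distance <= the configured cutoff
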