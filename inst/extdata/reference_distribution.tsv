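key	value
total_pa_clusters	50616
genic_sites	35055
intergenic_sites	15561
genes_with_sites	15218
annotated_genes	25699
pct_genic	69.26
pct_intergenic	30.74
pct_three_prime_utr	79.07
pct_intron	15.07
pct_exon	4.99
pct_five_prime_utr	0.87
chr32_genes	8
chr32_sites	72
chr32_ratio	9
ratio_min	1.49
ratio_max	2.49
pct_cluster_one_site	35.34
pct_cluster_two_sites	34.47
pct_cluster_several_sites	30.19
pct_pas_bearing	89.87
pct_apa_genes	70.41
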