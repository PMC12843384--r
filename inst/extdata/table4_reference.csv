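feature_id,complexity_slope,intersection_time,anchor_label
dna_length,0.89,8.4,100 nt DNA string
gene_number,0.78,7.2,one peptide
pp_binding,0.81,8.5,one pair of bound proteins
build_energy,1.22,8.3,energy to build 33 amino acids
cell_volume,1.32,8.5,8 nm diameter micelle volume
metabolic_rate,0.90,NA,NA
volume_per_doubling,0.93,10.5,abiotic synthesis of 33 residues
mcbit,0.84,8.8,average mcbit of a 100 nt RNA string
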