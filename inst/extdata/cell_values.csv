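taxon,volume_um3,doubling_h,note
vertebrates,3000,30,HeLa canonical volume
invertebrates,1767,20,15 um diameter sphere
fungi,30,NA,budding yeast; no published doubling time in this compilation
bacteria,1.0,3,E. coli canonical volume
archaea,1.0,2.2,
jcvi_syn3a,NA,2,volume computed from the reported 0.4 um diameter
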