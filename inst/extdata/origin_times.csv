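taxon,gyr_bp_range,time_gyr_bp,note
archaea,3.3-3.5,3.4,
bacteria,3.3-3.5,3.42,
cyanobacteria,2.5-3.6,3.2,
red_algae,1.5-1.7,1.6,
green_algae,1.1-1.1,1.1,
fungi,1.1-2.06,1.46,
arthropods,0.48-0.53,0.5,
land_plants,0.45-0.5,0.47,
invertebrates,0.55-0.65,0.6,
vertebrates,0.45-0.55,0.5,
mammals,0.3-0.3,0.3,
jcvi_syn3a,3.5-4,3.75,minimal-cell LUCA surrogate; 4.0 used for the DNA-length analysis
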