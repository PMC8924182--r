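# Small end-to-end configuration: 2 species x 2 strains on 50 kb toy
# genomes, 100 capsules per dose at doses 0 and 5 uM. Every similarity,
# grouping and QC threshold keeps its standard default.
run_id: smoke
master_seed: 1
output_dir: cosag_smoke
n_species: 2
strains_per_species: 2
genome_length: 50000
n_capsules: 100
pma_doses: [0, 5]
viable_fraction: 0.7
reads_per_positive_capsule: 8000
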