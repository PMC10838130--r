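# extdata

`supplementary_cross_table.csv` (not shipped): the deposited cross
table of hybridizing Galliformes species pairs used by
`reproduce_study()` and the reproduction tests. Place it here before
installing to enable them. Expected layout (comma- or tab-delimited,
header required):

    species_a,species_b,outcome,divergence_my,source

with `outcome` one of the recognised fertility labels (see
`default_outcome_map()`), and `divergence_my` the pair's median
divergence time in million years.
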