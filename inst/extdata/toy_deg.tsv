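gene_id	direction
g1	up
g2	up
g3	down
g6	up
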