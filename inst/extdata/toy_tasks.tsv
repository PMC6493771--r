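task_name	metabolite_id	compartment	phenotype
D_SYN	D	c	demo
B_SYN	B	c	demo
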