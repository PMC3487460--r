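gene_id	viability	segregation_flag
gCfx	NG	complete
gCt	NG	complete
gOx1	NG	complete
gOx2	NG	complete
gGs1	G	complete
gGs2	G	complete
gGt	G	complete
gGd	G	complete
gNif	G	complete
gResp	G	complete
gNif	NG	incomplete
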