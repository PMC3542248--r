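term_id	term_name
GO:0001666	response to hypoxia
GO:0019825	oxygen binding
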