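term_id	term_name
GO:0009411	response to UV
GO:0006749	glutathione metabolic process
GO:0006979	response to oxidative stress
GO:0006200	ATP catabolic process
GO:0007031	peroxisome organization
GO:0030163	protein catabolic process
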