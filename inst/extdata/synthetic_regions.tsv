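sequence_id	start	end	status
synthetic_A	28	34	amyloid
synthetic_A	61	67	amyloid
synthetic_B	30	41	amyloid
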