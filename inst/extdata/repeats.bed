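toy1	2000	2968	LTR5Hs	0	+
toy1	2968	8032	HERVK-int	0	+
toy1	2000	9000	repeat_body	0	+
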