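IRDS	interferon-related DNA damage resistance signature (8 genes)	STAT1	IFI44	IFIT3	OAS1	IFIT1	ISG15	MX1	USP18
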