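rule_id	marker	phases	expectation	threshold_mode	threshold_value
Ki67_high_in_S	Ki67	S	high	quantile	0.10
CDT1_neg_after_S	CDT1	G2+M	negative	quantile	0.55
pRb_high_in_G2	pRbS780	G2	high	quantile	0.05
PLK1_low_in_G0G1	PLK1	G0G1	low	quantile	0.90
SLBP_low_in_G2	SLBP	G2	low	quantile	0.50
Geminin_low_in_G0G1	Geminin	G0G1	low	quantile	0.55
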