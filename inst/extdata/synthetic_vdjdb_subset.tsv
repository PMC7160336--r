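gene	cdr3	antigen.species	v.segm	j.segm
TRB	CASSLAPGATNEKLFF	InfluenzaA	TRBV5-1*01	TRBJ1-4*01
TRB	CASSIRSSYEQYF	CMV	TRBV19*01	TRBJ2-7*01
TRB	CASSPGQGDNEQFF	EBV	TRBV4-1*01	TRBJ2-1*01
TRB	CASSFEGGAYEQYF	EBV	TRBV12-3*01	TRBJ2-7*01
TRA	CAVRDGGSQGNLIF	CMV	TRAV1-2*01	TRAJ42*01
TRB	CASSYSGDPDTQYF	HIV-1	TRBV6-5*01	TRBJ2-3*01
TRB	CASSVDGNEQFF	HomoSapiens	TRBV9*01	TRBJ2-1*01
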