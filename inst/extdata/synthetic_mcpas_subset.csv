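CDR3.beta.aa,Pathology,TRBV,TRBJ
CASSLAPGATNEKLFF,Influenza,TRBV5-1,TRBJ1-4
CASSIRSSYEQYF,Cytomegalovirus (CMV),TRBV19,TRBJ2-7
CASSIRSSYEQYF,Epstein Barr virus (EBV),TRBV19,TRBJ2-7
CASSPGQGDNEQFF,Epstein Barr virus (EBV),TRBV4-1,TRBJ2-1
CSARDRTGNGYTF,Multiple sclerosis (MS),TRBV20-1,TRBJ1-2
CASSQETQYF,Multiple sclerosis (MS),TRBV6-5,TRBJ2-5
CASSLGQAYEQYF,Influenza,TRBV27,TRBJ2-7
CASRDRDRVNTEAFF,Cytomegalovirus (CMV),TRBV6-1,TRBJ1-1
CASSPTSGGQETQYF,Psoriatic arthritis,TRBV28,TRBJ2-5
CATSDGDEQFF,Celiac disease,TRBV24-1,TRBJ2-1
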