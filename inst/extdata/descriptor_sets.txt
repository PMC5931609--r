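# Molecular-descriptor name lists (MOE naming) used for ABC-transporter
# substrate classification. One set per line: "<set name>: <comma-separated
# descriptor names>". DD17 is the decorrelated union of the three
# per-transporter sets.
P-gp: apol, chi0_C, chi0v_C, chi1_C, rings, PEOE_VSA-5, PEOE_VSA_POL, PEOE_VSA_PPOS, SlogP_VSA0, SMR_VSA2, TPSA, opr_brigid
MRP1: a_count, a_hyd, chi1v, opr_nring, PEOE_VSA+3, PEOE_VSA+5, PEOE_VSA-4, PEOE_VSA-6, Q_VSA_PNEG, vsa_acc
BCRP: a_count, a_hyd, a_nC, a_nH, chi1v, SlogP_VSA1, SlogP_VSA2, SlogP_VSA8, SMR_VSA1, SMR_VSA6, VDistMa
DD17: apol, opr_brigid, PEOE_VSA+3, PEOE_VSA+5, PEOE_VSA-4, PEOE_VSA-5, PEOE_VSA-6, PEOE_VSA_POL, Q_VSA_PNEG, SlogP_VSA0, SlogP_VSA1, SlogP_VSA2, SlogP_VSA8, SMR_VSA1, SMR_VSA2, SMR_VSA6, vsa_acc
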