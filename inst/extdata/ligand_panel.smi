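CCCn1c(C)c(C(=O)c2cccc3ccccc23)c2ccccc21 JWH-015
CCCn1cc(C(=O)c2cccc3ccccc23)c2ccccc21 JWH-072
CCCCCn1cc(C(=O)c2cccc3ccccc23)c2ccccc21 JWH-018
CCCCCCC(C)(C)c1ccc(C2CCCC(O)C2)c(O)c1 CP-47497
CCOP(=S)(OCC)Oc1cc(C)nc(C(C)C)n1 diazinon
CCN(CC)c1nc(C)cc(OP(=S)(OC)OC)n1 pirimiphos-methyl
COP(=S)(OC)SCn1nnc2ccccc2c1=O azinphos-methyl
CCOP(=S)(OCC)Oc1ccc(cc1)[N+](=O)[O-] parathion
CCOC(=O)CC(SP(=S)(OC)OC)C(=O)OCC malathion
CNC(=O)CSP(=S)(OC)OC dimethoate
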