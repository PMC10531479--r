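alert_id,role,smiles,name
TA662,positive,CCNCC,diethylamine
TA662,negative,CCN,ethylamine
TA665,positive,CCCN,propan-1-amine
TA665,negative,Nc1ccccc1,aniline
TA642,positive,C[NH3+],methylammonium
TA642,negative,CN,methylamine
TA628,positive,C=C[N+](=O)[O-],nitroethylene
TA628,negative,CC[N+](=O)[O-],nitroethane
TA11521,positive,c1ccc(cc1)[N+](=O)[O-],nitrobenzene
TA11521,negative,C[N+](=O)[O-],nitromethane
TA667,positive,C=CC(=O)OC,methyl acrylate
TA667,negative,C=CCC,but-1-ene
TA617,positive,COP(=O)(OC)OC,trimethyl phosphate
TA617,negative,CP(=O)(O)O,methylphosphonic acid
TA626,positive,C=CC#N,acrylonitrile
TA626,negative,CCC#N,propionitrile
TA631,positive,C=CC(=O)O,acrylic acid
TA631,negative,CCC(=O)O,propionic acid
TA1181,positive,CC(=O)NC,N-methylacetamide
TA1181,negative,CC(=O)N,acetamide
TA1176,positive,CC(=O)O,acetic acid
TA1176,negative,CC(=O)OC,methyl acetate
TA659,positive,CCO,ethanol
TA659,negative,Oc1ccccc1,phenol
TA638,positive,FCc1ccccc1,benzyl fluoride
TA638,negative,Fc1ccccc1,fluorobenzene
TA634,positive,CCF,fluoroethane
TA634,negative,CCCl,chloroethane
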