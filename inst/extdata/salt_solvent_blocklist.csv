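"salt_id","smiles","class","name"
"SS-0001","[Na+]","counterion","sodium"
"SS-0002","[K+]","counterion","potassium"
"SS-0003","[Li+]","counterion","lithium"
"SS-0004","[Cs+]","counterion","cesium"
"SS-0005","[Ca+2]","counterion","calcium"
"SS-0006","[Mg+2]","counterion","magnesium"
"SS-0007","[Ba+2]","counterion","barium"
"SS-0008","[Sr+2]","counterion","strontium"
"SS-0009","[Zn+2]","counterion","zinc"
"SS-0010","[Al+3]","counterion","aluminium"
"SS-0011","[Fe+2]","counterion","iron(II)"
"SS-0012","[Fe+3]","counterion","iron(III)"
"SS-0013","[Mn+2]","counterion","manganese"
"SS-0014","[Cu+2]","counterion","copper"
"SS-0015","[Ag+]","counterion","silver"
"SS-0016","[NH4+]","counterion","ammonium"
"SS-0017","[F-]","counterion","fluoride"
"SS-0018","[Cl-]","counterion","chloride"
"SS-0019","[Br-]","counterion","bromide"
"SS-0020","[I-]","counterion","iodide"
"SS-0021","OS(=O)(=O)O","counterion","sulfate/bisulfate"
"SS-0022","O[N+]([O-])=O","counterion","nitrate"
"SS-0023","OP(=O)(O)O","counterion","phosphate"
"SS-0024","OC(O)=O","counterion","carbonate/bicarbonate"
"SS-0025","CC(O)=O","counterion","acetate/acetic acid"
"SS-0026","OC=O","counterion","formate/formic acid"
"SS-0027","OC(=O)C(O)=O","counterion","oxalate"
"SS-0028","OC(=O)CC(O)(CC(O)=O)C(O)=O","counterion","citrate"
"SS-0029","OC(C(O)C(O)=O)C(O)=O","counterion","tartrate"
"SS-0030","OC(=O)C=CC(O)=O","counterion","maleate/fumarate"
"SS-0031","OC(=O)CCC(O)=O","counterion","succinate"
"SS-0032","OC(=O)c1ccccc1","counterion","benzoate"
"SS-0033","OC(=O)c1ccccc1O","counterion","salicylate"
"SS-0034","CS(O)(=O)=O","counterion","methanesulfonate"
"SS-0035","Cc1ccc(cc1)S(O)(=O)=O","counterion","p-toluenesulfonate"
"SS-0036","OS(=O)(=O)c1ccccc1","counterion","benzenesulfonate"
"SS-0037","OS(=O)(=O)C(F)(F)F","counterion","triflate"
"SS-0038","OC(=O)C(F)(F)F","counterion","trifluoroacetate"
"SS-0039","CC(O)C(O)=O","counterion","lactate"
"SS-0040","OC(=O)CC(O)C(O)=O","counterion","malate"
"SS-0041","OCC(O)C(O)C(O)C(O)C(O)=O","counterion","gluconate"
"SS-0042","OCl(=O)(=O)=O","counterion","perchlorate"
"SS-0043","SC#N","counterion","thiocyanate"
"SS-0044","OC(=O)CCCCC(O)=O","counterion","adipate"
"SS-0045","OC(=O)C(O)c1ccccc1","counterion","mandelate"
"SS-0046","OBr(=O)=O","counterion","bromate"
"SS-0047","O","solvent","water"
"SS-0048","CO","solvent","methanol"
"SS-0049","CCO","solvent","ethanol"
"SS-0050","CC(C)O","solvent","2-propanol"
"SS-0051","CC(C)=O","solvent","acetone"
"SS-0052","CC#N","solvent","acetonitrile"
"SS-0053","CS(C)=O","solvent","dimethyl sulfoxide"
"SS-0054","CN(C)C=O","solvent","N,N-dimethylformamide"
"SS-0055","C1CCOC1","solvent","tetrahydrofuran"
"SS-0056","C1COCCO1","solvent","1,4-dioxane"
"SS-0057","CCOCC","solvent","diethyl ether"
"SS-0058","CCOC(C)=O","solvent","ethyl acetate"
"SS-0059","ClCCl","solvent","dichloromethane"
"SS-0060","ClC(Cl)Cl","solvent","chloroform"
"SS-0061","CCCCCC","solvent","n-hexane"
"SS-0062","C1CCCCC1","solvent","cyclohexane"
"SS-0063","Cc1ccccc1","solvent","toluene"
"SS-0064","c1ccncc1","solvent","pyridine"
"SS-0065","OCC(O)CO","solvent","glycerol"
"SS-0066","OCCO","solvent","ethylene glycol"
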