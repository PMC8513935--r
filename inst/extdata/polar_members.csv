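class,member,smiles
ethers,tetrahydrofuran,C1CCOC1
ethers,diethyl ether,CCOCC
ethers,di-n-butyl ether,CCCCOCCCC
nitriles,acetonitrile,CC#N
nitriles,propionitrile,CCC#N
nitriles,butyronitrile,CCCC#N
ketones,acetone,CC(C)=O
ketones,butanone,CCC(C)=O
ketones,cyclohexanone,O=C1CCCCC1
alcohols,methanol,CO
alcohols,ethanol,CCO
alcohols,propan-1-ol,CCCO
alcohols,butan-1-ol,CCCCO
alcohols,pentan-1-ol,CCCCCO
alcohols,hexan-1-ol,CCCCCCO
alcohols,heptan-1-ol,CCCCCCCO
alcohols,octan-1-ol,CCCCCCCCO
alcohols,decan-1-ol,CCCCCCCCCCO
alcohols,propan-2-ol,CC(O)C
alcohols,butan-2-ol,CCC(O)C
alcohols,2-methylpropan-1-ol,CC(C)CO
alcohols,2-methylpropan-2-ol,CC(C)(C)O
alcohols,3-methylbutan-1-ol,CC(C)CCO
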