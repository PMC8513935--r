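n_alkyl,beta,units,provenance
0,2.00,dimensionless,experimental_1to1
1,2.20,dimensionless,experimental_1to1
2,2.40,dimensionless,experimental_1to1
3,2.70,dimensionless,experimental_1to1
6,3.10,dimensionless,experimental_1to1
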