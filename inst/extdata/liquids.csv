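name,molar_mass,density
water,18.015,0.997
benzene,78.11,0.874
toluene,92.14,0.867
dichloromethane,84.93,1.33
chloroform,119.38,1.49
"1,2-dichloroethane",98.96,1.253
carbon tetrachloride,153.82,1.594
hexadecane,226.44,0.773
hexane,86.18,0.655
cyclohexane,84.16,0.774
acetone,58.08,0.784
acetonitrile,41.05,0.786
ethanol,46.07,0.789
methanol,32.04,0.792
tetrahydrofuran,72.11,0.889
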