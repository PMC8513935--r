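synonym,canonical
n-hexadecane,hexadecane
n-hexane,hexane
tetrachloromethane,carbon tetrachloride
ccl4,carbon tetrachloride
methylene chloride,dichloromethane
dcm,dichloromethane
ch2cl2,dichloromethane
trichloromethane,chloroform
chcl3,chloroform
dce,"1,2-dichloroethane"
ethylene dichloride,"1,2-dichloroethane"
perfluorohexane,perfluoroalkane
thf,tetrahydrofuran
ether,diethyl ether
di-n-butylether,di-n-butyl ether
dibutyl ether,di-n-butyl ether
isopropanol,propan-2-ol
2-propanol,propan-2-ol
1-propanol,propan-1-ol
n-propanol,propan-1-ol
1-butanol,butan-1-ol
n-butanol,butan-1-ol
2-butanol,butan-2-ol
tert-butanol,2-methylpropan-2-ol
t-butanol,2-methylpropan-2-ol
isobutanol,2-methylpropan-1-ol
1-pentanol,pentan-1-ol
1-hexanol,hexan-1-ol
1-heptanol,heptan-1-ol
1-octanol,octan-1-ol
octanol,octan-1-ol
1-decanol,decan-1-ol
mek,butanone
2-butanone,butanone
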