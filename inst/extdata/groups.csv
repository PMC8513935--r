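code,label,role,value,count,domain,provenance
[CX4H4],CH(sp3),donor,1.20,4,nonpolar,experimental_1to1
[CX4H4],CH(sp3),acceptor,0.60,4,nonpolar,experimental_1to1
[CX4H3],CH(sp3),donor,1.20,3,nonpolar,experimental_1to1
[CX4H3],CH(sp3),acceptor,0.60,3,nonpolar,experimental_1to1
[CX4H2],CH(sp3),donor,1.20,2,nonpolar,experimental_1to1
[CX4H2],CH(sp3),acceptor,0.60,2,nonpolar,experimental_1to1
[CX4H1],CH(sp3),donor,1.20,1,nonpolar,experimental_1to1
[CX4H1],CH(sp3),acceptor,0.60,1,nonpolar,experimental_1to1
[CX4H0],C(quaternary),none,NA,0,nonpolar,experimental_1to1
[CX4H3;Cl],CH(sp3 polarised),donor,1.60,3,nonpolar,optimised
[CX4H3;Cl],CH(sp3),acceptor,0.60,3,nonpolar,experimental_1to1
[CX4H2;Cl],CH(sp3 polarised),donor,1.60,2,nonpolar,optimised
[CX4H2;Cl],CH(sp3),acceptor,0.60,2,nonpolar,experimental_1to1
[CX4H1;Cl],CH(sp3 polarised),donor,1.60,1,nonpolar,optimised
[CX4H1;Cl],CH(sp3),acceptor,0.60,1,nonpolar,experimental_1to1
[cH],CH(aromatic),donor,1.40,1,nonpolar,optimised
[cH],pi(aromatic CH),acceptor,0.70,2,nonpolar,optimised
[c;alkyl],pi(aromatic C-R),acceptor,0.88,2,nonpolar,optimised
[CX3H2],CH(sp2),donor,1.20,2,nonpolar,experimental_1to1
[CX3H2],CH(sp2),acceptor,0.60,2,nonpolar,experimental_1to1
[CX3H2],pi(C=C),acceptor,0.60,2,nonpolar,optimised
[CX3H1],CH(sp2),donor,1.20,1,nonpolar,experimental_1to1
[CX3H1],CH(sp2),acceptor,0.60,1,nonpolar,experimental_1to1
[CX3H1],pi(C=C),acceptor,0.60,2,nonpolar,optimised
[CX3H0],pi(C=C),acceptor,0.60,2,nonpolar,optimised
[CX3H0;=O],pi(C=O),acceptor,0.60,2,nonpolar,optimised
[OX1;=C],lone pair(C=O),acceptor,5.80,1,polar,experimental_1to1
[OX1;=C],lone pair(C=O),acceptor,3.80,1,polar,optimised
[OX2H2],OH(water),donor,2.80,2,polar,experimental_1to1
[OX2H2],lone pair(water),acceptor,4.50,2,polar,experimental_1to1
[OX2H1],OH(alcohol),donor,2.70,1,polar,experimental_1to1
[OX2H1],lone pair(O),acceptor,5.30,1,polar,experimental_1to1
[OX2H1],lone pair(O),acceptor,3.98,1,polar,optimised
[OX2H0],lone pair(O),acceptor,5.30,1,polar,experimental_1to1
[OX2H0],lone pair(O),acceptor,3.98,1,polar,optimised
[CX2],pi(sp C),acceptor,0.60,4,nonpolar,optimised
[NX1],lone pair(nitrile N),acceptor,5.15,1,polar,experimental_1to1
[Cl;C],Cl(polar site),acceptor,2.30,1,polar,experimental_1to1
[Cl;C],Cl(nonpolar),donor,1.20,2,nonpolar,experimental_1to1
[Cl;C],Cl(nonpolar),acceptor,0.60,2,nonpolar,experimental_1to1
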