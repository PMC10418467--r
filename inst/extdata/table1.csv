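id,smiles,ic50,pic50_exp,class_exp
5,NC1=NC(NC2=CC=CC(NC(C3=CC=CC(NC4=CC=NC5=CC=CC=C54)=C3)=O)=C2)=CC(C)=N1,1,5.000,A
12,C1(OCC2=CC=CC=C2)=CC=CC(CNCC3CCNCC3)=C1,14.7,3.833,I
13a,CN(CCN(C)C)CC1=C(C=CCC1)SC2=C3C(C=CC=C3)=CC=C2,0.3,5.523,A
15a,O=S(N)(C1=CC=C(CCNCC(C=C2)=CC=C2OCC=C)C=C1)=O,8.5,4.071,I
16a,OC1=CC(O)=C(C(CC2=NNC(C3=CC=C(C)C=C3)=C2)=O)C(O)=C1,4.9,4.310,I
17a,O=C(OCC)C1=C(C2=CC=CC=C2C3=CC=CC=C43)C4=CC5=[N+]1CCC6=C5C=CC=C6,5.3,4.276,I
23a,O=C(N([H])CCN(C)C)C1=C(C=CC=C1)SC2=CC=CC3=C2C=CC=C3,>20,3.699,I
23b,O=C(N([H])CCN(C)C)C1=C(C=CC=C1)SC2=CC=CC=C2,>5,4.301,I
23d,O=C(N([H])CCN(C)C)C1=C(C=CC=C1)SC2=CC=C(C)C(Cl)=C2,>5,4.301,I
24a,[H]C(N([H])CCN(C)C)C1=C(C=CC=C1)SC2=CC=CC3=C2C=CC=C3,3.4,4.469,I
24b,[H]C(N([H])CCN(C)C)C1=C(C=CC=C1)SC2=CC=CC=C2,>5,4.301,I
24c,[H]C(N([H])CCN(C)C)C1=C(C=CC=C1)SC2=CC=C(C)C(F)=C2,4.5,4.347,I
24d,[H]C(N([H])CCN(C)C)C1=C(C=CC=C1)SC2=CC=C(C)C(Cl)=C2,5.4,4.268,I
25c,[H]C(N(C)CCN(C)C)C1=C(C=CC=C1)SC2=CC=C(C)C(F)=C2,0.071,6.149,A
25d,[H]C(N(C)CCN(C)C)C1=C(C=CC=C1)SC2=CC=C(C)C(Cl)=C2,0.039,8.959,A
28d,[H]C(N(C)CCN([H])[H])C1=C(C=CC=C1)SC2=CC=C(C)C(Cl)=C2,0.00011,8.959,A
31d,CNCCN(CC1=CC=CC=C1SC2=CC=CC=C2Cl)C,0.0006,8.222,A
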