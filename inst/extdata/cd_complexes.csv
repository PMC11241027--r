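id,complex,homo_ev,lumo_ev,gap_ev,binding_score_kjmol,binding_affinity_kjmol
1,Caffeic acid-in,-9.1890,-1.0514,-8.1376,-4.5,-51.1831
2,Camphor-in,-10.1147,0.0704,-10.1851,-3.9,-34.4419
3,D-Limonene-in,-9.3119,0.0092,-9.3211,-3.5,-44.2580
4,Eucalyptol-in,-9.9785,0.1605,-10.139,-4.0,-52.1555
5,Eugenol-up,-8.9658,-0.1518,-8.8140,-4.0,-35.1691
6,Gallic acid-up,-9.5087,-1.2760,-8.2327,-5.0,-35.6459
7,Geranial-up,-9.5651,-0.2514,-9.3137,-3.2,-58.3673
8,Heptanol-up,-10.2024,-0.1426,-10.0598,-2.8,-26.6948
9,Hydroxy Methyl Furfural-up,-9.2240,-0.4026,-8.8214,-3.7,-64.9081
10,Isoamyl acetate-up,-10.1978,-0.3113,-9.8865,-3.1,-66.5904
11,Maltol-up,-9.8792,-1.3000,-8.5792,-4.1,-64.6218
12,Menthol-in,-10.1733,-0.0167,-10.1566,-4.2,-57.9313
13,Neral-up,-9.7932,-0.4443,-9.3489,-3.4,-66.7781
14,P-Coumaric acid-in,-9.3920,-0.3048,-9.0872,-4.3,-63.3347
15,Pinellic acid-in,-9.8072,0.0819,-9.8891,-3.6,-63.3198
16,Sinapic acid-up,-9.1111,-1.1979,-7.9132,-4.6,-90.6849
17,Styrene-up,-9.4684,-0.4950,-8.9734,-2.9,-45.7564
18,Syringic acid-up,-9.2231,-0.9025,-8.3206,-4.6,-76.8800
19,Trans Ferulic acid-up,-9.0647,-1.4466,-7.6181,-4.4,-64.1563
20,Vanillic acid-in,-9.1477,-0.9277,-8.2200,-4.4,-76.3647
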