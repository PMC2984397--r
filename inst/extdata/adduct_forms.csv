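label,adduct_mz,n_imer,probability_pct
3 m + H,1.00728,3,1
4 m + H,1.00728,4,1
5 m + H,1.00728,5,1
3 m + Na,22.98977,3,1
4 m + Na,22.98977,4,1
5 m + Na,22.98977,5,1
m + H,1.00728,1,100
m-,0,1,10
2 m + H,1.00728,2,50
m + Na,22.98977,1,90
2 m + Na,22.98977,2,25
m + K,39.954,1,10
2 m + K,39.954,2,5
m-H,-1.00728,1,100
4 m + K,39.954,4,1
2 m-H,-1.00728,2,50
m + Form,44.9971,1,99
m-H2O,-18.01002,1,80
5 m + K,39.954,5,1
3 m-H,1.00728,3,1
4 m-H,-1.00728,4,1
5 m-H,-1.00728,5,1
2 m + Na-2H,20.9741,2,50
6 m + H,1.00728,6,1
7 m + H,1.00728,7,1
8 m + H,1.00728,8,1
m + H-H20,-17.01,1,1
m + Cl35,34.9689,1,12
m + Cl35[Cl37],36.9659,1,4
m + NH4,18.03437,1,1
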