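Reagent,DonorAbility,CoordBasicity,IonPairDissociation
LiI,28,5.0,0.10
LiBF4,10,1.2,0.35
LiClO4,9,1.0,0.40
LiOTf,8,0.8,0.50
LiNTf2,5,0.3,0.75
LiPF6,3,0.2,0.85
LiB(C6F5)4,1,0.05,0.99
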