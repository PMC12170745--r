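feature,value
sre,0.872596153846154
lre,1.91025641025641
gln,9.77000777000777
glnn,0.251032076789653
rln,35.534188034188
rlnn,0.844669990503324
rp,0.884615384615384
glv,1.24936525315313
rlv,0.164292497625831
re,2.33040750674512
lglre,0.355181084347751
hglre,7.56604506604507
srlgle,0.307967064549819
srhgle,6.63071149529483
lrlgle,0.650928354053354
lrhgle,14.9143356643357
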