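name: population2
description: Fish-count bench population (study year 1995, auxiliary year 1993), printed summary parameters
N: 69
n: 15
lam: 0.0521739
mean_y: 4514.899
mean_x: 4591.072
mean_rx: 35
Sy2: 37199578
Sx2: 39881874
Srx2: 402.5
rho_yx: 0.9564207
rho_yrx: 0.7539346
rho_xrx: 0.7593837
lam400s: 6.544991
lam040s: 8.698631
lam004s: 0.747145
lam220s: 7.190264
lam202s: 1.157465
lam022s: 1.303701
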