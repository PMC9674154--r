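name: population1
description: Fish-count bench population (study year 1995, auxiliary year 1994), printed summary parameters
N: 69
n: 15
lam: 0.0521739
mean_y: 4514.899
mean_x: 4954.435
mean_rx: 35
Sy2: 37199578
Sx2: 49829270
Srx2: 402.5
rho_yx: 0.9601401
rho_yrx: 0.7688589
rho_xrx: 0.7543462
lam400s: 6.544991
lam040s: 8.69773
lam004s: 0.747145
lam220s: 7.053057
lam202s: 1.159139
lam022s: 1.298094
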