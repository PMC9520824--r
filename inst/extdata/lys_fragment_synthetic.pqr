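REMARK Synthetic lysine side-chain probe fragment (protonated ammonium,
REMARK net charge +1 |e|). Coarse stand-in geometry with Amber-like
REMARK charges/radii, not a published parameterization.
ATOM      1  CE  LYS A   1       0.000   0.000   0.000 -0.0140 1.9080
ATOM      2  HE2 LYS A   1       0.360   0.520   0.880  0.1135 1.1000
ATOM      3  HE3 LYS A   1       0.360   0.520  -0.880  0.1135 1.1000
ATOM      4  NZ  LYS A   1      -1.470   0.000   0.000 -0.3454 1.8240
ATOM      5  HZ1 LYS A   1      -1.830  -0.490   0.820  0.3400 0.6000
ATOM      6  HZ2 LYS A   1      -1.830  -0.490  -0.820  0.3400 0.6000
ATOM      7  HZ3 LYS A   1      -1.830   0.950   0.000  0.3400 0.6000
ATOM      8  HB  LYS A   1       0.380  -1.010   0.100  0.1124 1.1000
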