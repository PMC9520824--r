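REMARK Synthetic guanidiniocarbonyl-pyrrole (GCP) probe fragment.
REMARK Coarse stand-in geometry with a net charge of +1 |e| (protonated
REMARK acylguanidine); charges/radii are plausible Amber-like values,
REMARK not a published parameterization.
ATOM      1  N1  GCP A   1       0.000   0.000   0.000 -0.5600 1.8240
ATOM      2  C1  GCP A   1       1.340   0.150   0.000  0.7400 1.9080
ATOM      3  N2  GCP A   1       2.180   1.210   0.000 -0.6200 1.8240
ATOM      4  N3  GCP A   1       1.900  -1.060   0.000 -0.6200 1.8240
ATOM      5  H1  GCP A   1       3.170   1.150   0.000  0.4400 0.6000
ATOM      6  H2  GCP A   1       1.800   2.120   0.000  0.4400 0.6000
ATOM      7  H3  GCP A   1       2.900  -1.130   0.000  0.4400 0.6000
ATOM      8  H4  GCP A   1       1.350  -1.900   0.000  0.4400 0.6000
ATOM      9  C2  GCP A   1      -0.800  -1.120   0.000  0.6300 1.9080
ATOM     10  O1  GCP A   1      -0.350  -2.260   0.000 -0.5500 1.6612
ATOM     11  C3  GCP A   1      -2.240  -0.910   0.000 -0.1100 1.9080
ATOM     12  H5  GCP A   1      -0.400   0.880   0.000  0.3300 0.6000
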