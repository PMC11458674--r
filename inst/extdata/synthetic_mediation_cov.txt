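# synthetic_mediation_cov: covariance input generated from a
# known 3-factor mediation model (synthetic data, not empirical)
N 547
sd 0.8052 1.1216 0.9358 1.2971 0.9597 1.5088 1.1745 0.7895 1.1218
1.0000
0.3851 1.0000
0.2366 0.3479 1.0000
0.0945 0.1390 0.0854 1.0000
0.0781 0.1149 0.0706 0.4652 1.0000
0.0914 0.1344 0.0826 0.5442 0.4497 1.0000
0.1371 0.2017 0.1239 0.1725 0.1426 0.1668 1.0000
0.1477 0.2173 0.1335 0.1859 0.1536 0.1797 0.3042 1.0000
0.1177 0.1731 0.1063 0.1481 0.1224 0.1432 0.2424 0.2611 1.0000
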