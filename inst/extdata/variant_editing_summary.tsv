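variant	a5_efficiency_pct	window	bystander_sum	c5_over_a5
ABE8e	44.0	A2-A10	NA	NA
S109F	42.3	A3-A7	NA	NA
N119Q	47.8	A3-A9	NA	NA
N119D	46.8	A3-A10	NA	NA
N119C	48.6	A3-A10	NA	NA
N122F	48.1	A2-A9	NA	NA
N122L	46.6	A2-A9	NA	NA
N122V	47.9	A2-A9	NA	NA
N122A	41.0	A2-A9	NA	NA
D147K	53.1	A2-A9	NA	NA
Y149L	45.1	A3-A7	NA	NA
Y149I	40.6	A3-A7	NA	NA
Y149M	45.9	A3-A7	NA	NA
Y149V	42.4	A3-A7	0.18	0.0090
S109F_Y149V	33.8	A3-A6	NA	NA
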