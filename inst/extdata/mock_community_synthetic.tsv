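id	copy_number	abundance
org1	4	0.0816326530612245
org2	7	0.142857142857143
org3_v1	6	0.122448979591837
org3_v2	1	0.0204081632653061
org4	5	0.102040816326531
org5	4	0.0816326530612245
org6	6	0.122448979591837
org7	6	0.122448979591837
org8	10	0.204081632653061
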