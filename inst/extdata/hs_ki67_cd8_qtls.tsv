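phenotype	chrom	start	end	rmip
cd8_in_cd3	1	59.2	59.9	0.31
ki67	1	132.7	137.7	0.4
cd8_in_cd3	3	126.9	129.5	0.59
ki67	4	40.4	49.8	0.26
ki67	5	71.2	76.8	0.68
cd8_in_cd3	5	70.8	76.8	0.2
cd8_in_cd3	5	113.6	114.7	0.94
ki67	6	68.8	74.8	0.22
cd8_in_cd3	6	68.8	73.7	0.94
ki67	6	127.1	127.8	0.27
cd8_in_cd3	7	47.9	51.8	0.25
cd8_in_cd3	7	118.4	122.6	0.36
cd8_in_cd3	10	38.3	40.3	0.2
ki67	10	38.3	45.3	0.26
cd8_in_cd3	12	26.6	30.9	0.77
ki67	13	35.2	37.7	0.53
cd8_in_cd3	13	36.1	37.7	0.35
ki67	13	110.6	119.2	0.49
ki67	16	34.4	35.7	0.67
cd8_in_cd3	16	34.8	36.6	0.3
cd8_in_cd3	17	33.7	34.5	1
cd8_in_cd3	17	43.6	49.6	0.58
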