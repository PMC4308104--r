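resolved_genotype	n	total_copies
*1/*5	1	1
*2/*5	1	1
*1/*2	3	2
*1/*4	1	2
*2/*4	1	2
*2/*10	2	2
(*1/*1)x3	1	3
(*2/*2)x3	1	3
*1/*2x2	6	3
*1/*17x2	1	3
*2/*4x2	1	3
*1x2/*4	1	3
*2x2/*17	1	3
*1/*10x2	5	3
*2/*10x2	2	3
*1/*10x3	3	4
(*10/*10)x4	6	4
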