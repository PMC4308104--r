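genotype	n
*3/*4	2
*4/*4	7
*4/*5	1
*4/*6	1
*3/*17	1
*4/*10	2
*4/*17	1
*4/*41	7
*5/*10	1
*5/*17	3
*1/*1	30
*1/*2	41
*1/*3	5
*1/*4	16
*1/*5	7
*1/*6	2
*1/*10	6
*1/*17	6
*1/*41	8
*1x2/*4	2
*1/*10x2	1
*1/*17x2	1
*2/*2	11
*2/*4	18
*2/*4x3	1
*2/*5	6
*2/*10	4
*2/*17	5
*2/*41	5
*10/*17	2
*10x2/*41	1
*17/*17	3
*17/*41	2
*41/*41	1
*1/*1x2	2
*1x2/*2	2
*1/*2x2	2
*2x2/*10	1
*2x2/*2	1
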