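sample_id	genotype
NA18564	*1/*10x2
NA18532	(*10/*10)x4
NA18545	(*10/*10)x4
NA18944	(*10/*10)x4
NA18960	(*10/*10)x4
NA18603	(*10/*10)x4
NA18561	(*10/*10)x4
NA18959	*2/*10x2
NA18537	*1/*10x2
NA18542	*1/*10x2
NA18524	*1/*10x3
NA18526	*1/*10x3
NA18563	*1/*10x2
NA18947	*1/*10x2
GM17221	*1x2/*2
GM02016	*2x2/*17
GM17298	(*1/*1)xN
GM17232	(*2/*2)xN
GM17244	*2/*4
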