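origin_set	origin_median	target_chromosome	cross_median
ChrSi09beg	4.53	chrLem4B	0.10
ChrSi09beg	4.53	chrLem4A	0.08
ChrSi09beg	4.53	chrWoa5	0.06
ChrSi09end	3.69	chrLem16A	0.05
ChrSi09end	3.69	chrLem16B	0.05
ChrSi09end	3.69	chrWoa16	0.05
ChrSp19	5.01	chrLem17B	0.08
ChrSp19	5.01	chrLem20A	0.07
ChrSp19	5.01	chrLem20B	0.10
ChrSp19	5.01	chrWoa4	0.08
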