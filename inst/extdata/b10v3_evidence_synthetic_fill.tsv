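contig_id	source	chromosome
ctg775	markers	Chr5
ctg775	scaffold:9930	Chr5_9930
ctg775	scaffold:Gy14	Chr5_Gy14
ctg775	blastp:9930	Chr5
ctg775	blastp:gy14	Chr5
ctg775	dart	Chr5
ctg775	bac_fish	Chr5
ctg1000	markers	Chr6
ctg1000	scaffold:9930	Chr6_9930
ctg1000	scaffold:Gy14	Chr6_Gy14
ctg1000	blastp:9930	Chr6
ctg1000	blastp:gy14	Chr6
ctg1000	dart	Chr6
ctg1000	bac_fish	Chr6
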