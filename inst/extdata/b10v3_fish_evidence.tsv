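contig_id	source	chromosome
ctg2607	markers	Chr3
ctg2607	scaffold:9930	Chr3_9930
ctg2607	scaffold:Gy14	Chr3_Gy14
ctg2607	blastp:9930	Chr3
ctg2607	blastp:gy14	Chr3
ctg2607	dart	Chr3
ctg2607	bac_fish	Chr1
ctg105	markers	Chr2
ctg105	scaffold:9930	Chr2_9930
ctg105	scaffold:Gy14	Chr2_Gy14
ctg105	blastp:9930	Chr2
ctg105	blastp:gy14	Chr2
ctg105	dart	Chr2
ctg105	bac_fish	Chr2
ctg184	markers	Chr4
ctg184	scaffold:9930	Chr4_9930
ctg184	scaffold:Gy14	Chr4_Gy14
ctg184	blastp:9930	Chr4
ctg184	blastp:gy14	Chr4
ctg184	dart	Chr4
ctg184	bac_fish	Chr4
ctg197	markers	Chr5
ctg197	scaffold:9930	Chr5_9930
ctg197	scaffold:Gy14	Chr5_Gy14
ctg197	blastp:9930	Chr5
ctg197	blastp:gy14	Chr5
ctg197	dart	Chr5
ctg197	bac_fish	Chr5
ctg1673	markers	Chr5
ctg1673	scaffold:9930	Chr5_9930
ctg1673	scaffold:Gy14	Chr5_Gy14
ctg1673	blastp:9930	Chr5
ctg1673	blastp:gy14	Chr5
ctg1673	dart	Chr5
ctg1673	bac_fish	Chr5
ctg1047	markers	Chr7
ctg1047	scaffold:9930	Chr7_9930
ctg1047	scaffold:Gy14	Chr7_Gy14
ctg1047	blastp:9930	Chr7
ctg1047	blastp:gy14	Chr7
ctg1047	bac_fish	Chr7
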