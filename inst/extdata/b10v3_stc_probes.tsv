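probe_id	contig_id	published_consensus	bac_chromosome
STC1_Bam_024_D19_M13	ctg105	Chr2	Chr2
STC1_Bam_007_M21_M13	ctg184	Chr4	Chr4
STC1_Bam_022_G02_M13	ctg184	Chr4	Chr4
STC1_Bam_001_J07_M13	ctg184	Chr4	Chr3
STC1_Bam_065_A04_M13	ctg1673	Chr5	Chr5
STC1_Bam_002_E06_M13	ctg2607	Chr3	Chr1
STC1_Bam_041_H23_M13	ctg1047	Chr7	Chr7
STC1_Bam_002_L09_M13	ctg197	Chr5	Chr5
STC1_Bam_062_O16_M13	ctg775	Chr5	Chr5
STC1_Bam_072_K05_M13	ctg105	Chr2	Chr2
STC1_Bam_038_P19_M13	ctg1000	Chr6	Chr6
STC1_Bam_065_L02_M13	ctg775	Chr5	Chr5
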