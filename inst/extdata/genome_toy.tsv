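## synthetic 10-chromosome toy build for tests; 0-based half-open, bp
#name	length	centromere_start	centromere_end	is_sex
chr1	100000000	45000000	55000000	0
chr2	100000000	45000000	55000000	0
chr3	100000000	45000000	55000000	0
chr4	100000000	45000000	55000000	0
chr5	100000000	45000000	55000000	0
chr6	100000000	45000000	55000000	0
chr7	100000000	45000000	55000000	0
chr8	100000000	45000000	55000000	0
chr9	100000000	45000000	55000000	0
chr10	100000000	45000000	55000000	0
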