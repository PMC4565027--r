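chr1	1099	1150	peak1	2.5
chr1	1600	1700	peak2	1.0
chr1	9100	9200	peak3	3.0
chr1	30000	30100	peak4	-1.5
chr2	5100	5101	snp1	0.7
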