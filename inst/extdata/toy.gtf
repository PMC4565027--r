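chr1	toy	gene	1001	2500	.	+	.	gene_id "G1"; gene_name "SYMA";
chr1	toy	transcript	1001	2500	.	+	.	gene_id "G1"; transcript_id "G1.T1"; gene_name "SYMA";
chr1	toy	exon	1001	1500	.	+	.	gene_id "G1"; transcript_id "G1.T1"; gene_name "SYMA";
chr1	toy	exon	2001	2500	.	+	.	gene_id "G1"; transcript_id "G1.T1"; gene_name "SYMA";
chr1	toy	CDS	1101	1400	.	+	.	gene_id "G1"; transcript_id "G1.T1"; gene_name "SYMA";
chr1	toy	CDS	2001	2200	.	+	.	gene_id "G1"; transcript_id "G1.T1"; gene_name "SYMA";
chr1	toy	gene	8001	9000	.	-	.	gene_id "G2"; gene_name "SYMB";
chr1	toy	transcript	8001	9000	.	-	.	gene_id "G2"; transcript_id "G2.T1"; gene_name "SYMB";
chr1	toy	exon	8001	9000	.	-	.	gene_id "G2"; transcript_id "G2.T1"; gene_name "SYMB";
chr2	toy	gene	5001	6000	.	+	.	gene_id "G3"; gene_name "SYMC";
chr2	toy	transcript	5001	6000	.	+	.	gene_id "G3"; transcript_id "G3.T1"; gene_name "SYMC";
chr2	toy	exon	5001	6000	.	+	.	gene_id "G3"; transcript_id "G3.T1"; gene_name "SYMC";
chr2	toy	CDS	5101	5900	.	+	.	gene_id "G3"; transcript_id "G3.T1"; gene_name "SYMC";
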