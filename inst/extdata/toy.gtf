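##gff-version 2
toy1	erviso	exon	1	500	.	+	.	transcript_id "ERVK7.long"; gene_id "ERVK7"
toy1	erviso	exon	1201	1500	.	+	.	transcript_id "ERVK7.long"; gene_id "ERVK7"
toy1	erviso	exon	3001	8500	.	+	.	transcript_id "ERVK7.long"; gene_id "ERVK7"
toy1	erviso	exon	1090	1500	.	+	.	transcript_id "ERVK7.short"; gene_id "ERVK7"
toy1	erviso	exon	3001	8500	.	+	.	transcript_id "ERVK7.short"; gene_id "ERVK7"
toy1	erviso	exon	2301	5000	.	+	.	transcript_id "ERVK7.ltr"; gene_id "ERVK7"
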