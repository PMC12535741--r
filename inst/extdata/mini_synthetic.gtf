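chr17	synthetic	gene	21003	38612	.	+	.	gene_id "LNC0001"; gene_type "lincRNA"; gene_name "LNC0001";
chr5	synthetic	gene	1016	2459	.	-	.	gene_id "LNC0002"; gene_type "antisense"; gene_name "LNC0002";
chr1	synthetic	gene	49110	61117	.	+	.	gene_id "LNC0003"; gene_type "sense_intronic"; gene_name "LNC0003";
chr10	synthetic	gene	34756	52264	.	-	.	gene_id "LNC0004"; gene_type "sense_overlapping"; gene_name "LNC0004";
chr4	synthetic	gene	41578	46434	.	-	.	gene_id "LNC0005"; gene_type "processed_transcript"; gene_name "LNC0005";
chr18	synthetic	gene	15232	28148	.	-	.	gene_id "LNC0006"; gene_type "3prime_overlapping_ncRNA"; gene_name "LNC0006";
chr17	synthetic	gene	65101	83379	.	+	.	gene_id "LNC0007"; gene_type "lincRNA"; gene_name "LNC0007";
chr15	synthetic	gene	49055	62215	.	+	.	gene_id "LNC0008"; gene_type "antisense"; gene_name "LNC0008";
chr7	synthetic	gene	1149	17412	.	-	.	gene_id "PCG0001"; gene_type "protein_coding"; gene_name "PCG0001";
chr4	synthetic	gene	77104	80420	.	-	.	gene_id "PCG0002"; gene_type "protein_coding"; gene_name "PCG0002";
chr5	synthetic	gene	38676	48381	.	-	.	gene_id "PCG0003"; gene_type "protein_coding"; gene_name "PCG0003";
chr14	synthetic	gene	24309	38989	.	-	.	gene_id "PCG0004"; gene_type "protein_coding"; gene_name "PCG0004";
chr20	synthetic	gene	27912	41348	.	-	.	gene_id "PCG0005"; gene_type "protein_coding"; gene_name "PCG0005";
chr18	synthetic	gene	67793	82667	.	-	.	gene_id "PCG0006"; gene_type "protein_coding"; gene_name "PCG0006";
chr15	synthetic	gene	89099	90114	.	-	.	gene_id "PCG0007"; gene_type "protein_coding"; gene_name "PCG0007";
chr3	synthetic	gene	48481	49924	.	+	.	gene_id "PCG0008"; gene_type "protein_coding"; gene_name "PCG0008";
chr9	synthetic	gene	40550	41151	.	-	.	gene_id "PCG0009"; gene_type "protein_coding"; gene_name "PCG0009";
chr4	synthetic	gene	119419	125265	.	+	.	gene_id "PCG0010"; gene_type "protein_coding"; gene_name "PCG0010";
chr5	synthetic	gene	56833	67680	.	-	.	gene_id "PCG0011"; gene_type "protein_coding"; gene_name "PCG0011";
chr13	synthetic	gene	41870	51913	.	-	.	gene_id "PCG0012"; gene_type "protein_coding"; gene_name "PCG0012";
chr5	synthetic	gene	73940	92515	.	-	.	gene_id "PCG0013"; gene_type "protein_coding"; gene_name "PCG0013";
chr20	synthetic	gene	52117	56787	.	-	.	gene_id "PCG0014"; gene_type "protein_coding"; gene_name "PCG0014";
chr2	synthetic	gene	22240	38054	.	+	.	gene_id "PCG0015"; gene_type "protein_coding"; gene_name "PCG0015";
chr8	synthetic	gene	26851	33246	.	-	.	gene_id "PCG0016"; gene_type "protein_coding"; gene_name "PCG0016";
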