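gene_id	chrom	strand	start	end	start_codon
Gene01	D10	+	5e+05	520000	500500
Gene02	D10	-	957142.857142857	977142.857142857	976642.857142857
Gene03	D10	+	1414285.71428571	1434285.71428571	1414785.71428571
Gene04	D10	-	1871428.57142857	1891428.57142857	1890928.57142857
Gene05	D10	+	2328571.42857143	2348571.42857143	2329071.42857143
Gene06	D10	-	2785714.28571429	2805714.28571429	2805214.28571429
Gene07	D10	+	3242857.14285714	3262857.14285714	3243357.14285714
Gene08	D10	-	3700000	3720000	3719500
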