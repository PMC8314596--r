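cohort	ancestry	n	outcome	scale	estimate	se	ci_low	ci_high	p	direction	subtotal	z	row_type
AIDHS/SDS	SOUTH_ASIAN	2675	VITD	BETA	-0.006	0.014	NA	NA	6.98E-01	-	FALSE	NA	cohort
SIKH REPLICATION	SOUTH_ASIAN	2197	VITD	BETA	-0.001	0.009	NA	NA	8.96E-01	-	FALSE	NA	cohort
SOUTH ASIAN META	SOUTH_ASIAN	4872	VITD	BETA	-0.003	0.008	NA	NA	7.45E-01	-	TRUE	-0.367	subtotal
Twins UK	EUROPEAN	5335	VITD	BETA	0.0004	0.001	NA	NA	7.07E-01	+	FALSE	NA	cohort
1958 BC	EUROPEAN	5181	VITD	BETA	0.1322	0.056	NA	NA	1.90E-02	+	FALSE	NA	cohort
CCHS/CGPS/CIHDS	EUROPEAN	11665	VITD	BETA	-0.0080	0.007	NA	NA	2.35E-01	-	FALSE	NA	cohort
PREVEND	EUROPEAN	3649	VITD	BETA	-0.0154	0.031	NA	NA	6.20E-01	-	FALSE	NA	cohort
Meta-Analysis	COMBINED	30702	VITD	BETA	-0.0002	0.0001	NA	NA	8.29E-01	-	TRUE	-0.212	printed_meta
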