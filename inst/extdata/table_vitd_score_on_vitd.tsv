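cohort	ancestry	n	outcome	scale	estimate	se	ci_low	ci_high	p	direction	subtotal	z	row_type
AIDHS/SDS	SOUTH_ASIAN	2388	VITD	BETA	-0.042	0.012	NA	NA	2.70E-04	-	FALSE	NA	cohort
SIKH REPLICATION	SOUTH_ASIAN	1846	VITD	BETA	-0.025	0.009	NA	NA	4.00E-03	-	FALSE	NA	cohort
SOUTH ASIAN META	SOUTH_ASIAN	4234	VITD	BETA	-0.031	0.007	NA	NA	4.01E-06	-	TRUE	-4.61	subtotal
Twins UK	EUROPEAN	3679	VITD	BETA	-0.129	0.020	NA	NA	5.20E-11	-	FALSE	NA	cohort
1958 BC	EUROPEAN	4993	VITD	BETA	-0.035	0.005	NA	NA	4.20E-14	-	FALSE	NA	cohort
CCHS/CGPS/CIHDS	EUROPEAN	24581	VITD	BETA	-0.020	0.001	NA	NA	3.00E-39	-	FALSE	NA	cohort
PREVEND	EUROPEAN	3649	VITD	BETA	-0.021	0.002	NA	NA	3.70E-33	-	FALSE	NA	cohort
Meta-Analysis	COMBINED	41136	VITD	BETA	-0.021	0.001	NA	NA	7.92E-78	-	TRUE	-18.68	printed_meta
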