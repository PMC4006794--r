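gene	region	sites	S_snp	pi_snp	theta_snp	tajD_snp	S_indel	pi_indel	theta_indel	tajD_indel
Antp	promoter	512	9	0.0037	0.0055	-1.24	2	0.0006	0.0010	-1.20
salm	wing blade enhancer	432	12	0.0088	0.0090	-0.05	0
en	regulatory element	554	6	0.0031	0.0034	-0.36	0
Ubx	Bxd promoter	346	1	0.0008	0.0009	-0.29	0
ems	Abdominal enhancer	604	10	0.0043	0.0052	-0.68	0
Hb	promoter spacer	184	0				0
tll	promoter	399	9	0.0070	0.0071	-0.05	0
Act57B	promoter	489	12	0.0082	0.0077	0.24	2	0.0007	0.0013	-1.28
RpL29/CG30390	promoter	482	19	0.0108	0.0124	-0.53	4	0.0009	0.0026	-2.19
RpL30	promoter	563	9	0.0053	0.0048	0.35	0
Kr	promoter	492	6	0.0053	0.0037	1.47	0
Kr	CD1(a)	444	20	0.0138	0.0121	0.53	1	0.0002	0.0006	-1.16
Kr	CD1(b)	334	22	0.0124	0.0181	-1.17	2	0.0006	0.0016	-1.39
eve	promoter	373	6	0.0043	0.0050	-0.44	0
eve	promoter spacer	545	6	0.0036	0.0029	0.79	2	0.0003	0.0010	-1.40
eve	s2e	593	11	0.0051	0.0041	0.67	1	0.0001	0.0004	-0.87
eve	s3+7e	283	3	0.0024	0.0025	-0.05	2	0.0012	0.0016	-0.49
eve	s3+7e spacer	432	12	0.0088	0.0065	1.07	4	0.0009	0.0022	-1.41
eve	late element	386	8	0.0040	0.0046	-0.36	0
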