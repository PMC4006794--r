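location	state	latitude	frequency	fst_del	n_s2e	sites_s2e	pi_s2e	theta_s2e	fst_s2e
Homestead	FL	25° 2′	0.32		24	5	0.0020	0.0024
Merrit Island	FL	28° 3′	0.16	0.051	26	7	0.0024	0.0033	0
Jacksonville	FL	30° 2′	0.19	0.000	29	7	0.0022	0.0032	0
Eutawville	SC	33° 2′	0.20	0.000	26	5	0.0021	0.0024	0
Smithfield	NC	35° 3′	0.14	0.000	16	4	0.0024	0.0022	0
Richmond	VA	37° 3′	0.05	0.033	33	5	0.0018	0.0022	0
Churchville	MD	39° 3′	0.17	0.052	23	5	0.0018	0.0024	0.051
Middlefield	CT	41° 3′	0.09	0.017	37	5	0.0019	0.0022	0.007
Concord	MA	42° 0′	0.19	0.030	41	5	0.0014	0.0021	0.009
Whiting	VT	43° 6′	0.17	0.000	30	2	0.0015	0.0010	0
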