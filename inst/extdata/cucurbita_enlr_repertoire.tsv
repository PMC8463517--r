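species	accession	origin	n_enlr
C. argyrosperma	PI-438547	Belize	64
C. argyrosperma	PI-512114	Nicaragua	38
C. argyrosperma	PI-512115	Guatemala	45
C. argyrosperma	PI-451712	Mexico	75
C. argyrosperma	PI-202079	Mexico	46
C. cordata	GRIF-9445	Mexico	17
C. cordata	PI-653839	Mexico	35
C. ecuadorensis	PI-432441	Ecuador	26
C. ecuadorensis	PI-432443	Ecuador	16
C. ecuadorensis	GRIF-9446	Ecuador	36
C. ficifolia	CATIE-16038	Guatemala	44
C. ficifolia	CATIE-16575	Guatemala	48
C. foetidissima	PI-442197	Mexico	41
C. foetidissima	PI-532350	Mexico	34
C. foetidissima	PI-442201	Mexico	51
C. lundelliana	PI-438542	Belize	46
C. lundelliana	PI-540898	Honduras	52
C. lundelliana	PI-532357	Mexico	66
C. lundelliana	PI-636138	Belize	60
C. maxima	VIR-3202	Chile	32
C. maxima	BGV004558	Argentina	34
C. maxima	UPV035142	Angola	26
C. maxima	PI-458653	Argentina	21
C. moschata	PI-498429	Colombia	35
C. moschata	NIG-LOCAL	Nigeria	64
C. moschata	PI-653064	Nigeria	42
C. okeechobensis	PI-532363	Mexico	33
C. okeechobensis	PI-512105	Mexico	28
C. okeechobensis	PI-512106	Mexico	16
C. pedatifolia	PI-442341	Mexico	42
C. pedatifolia	PI-442290	Mexico	73
C. pedatifolia	PI-540737	Mexico	33
C. pepo	CATIE-18887	Mexico	41
C. pepo	CATIE-11368	Guatemala	34
C. pepo	BGV004370	Spain	10
C. pepo	BGV005380	Spain	10
C. pepo	PI-615111	USA	28
C. pepo	PI-532354	Mexico	71
C. pepo	PI-614701	Mexico	37
C. scabridifolia	PI-532392	Mexico	53
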