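class_label	is_full_length	C. argyrosperma	C. maxima	C. moschata	C. pepo	C. sororia
CNL	TRUE	3	14	28	5	9
TNL	TRUE	4	5	14	1	10
RNL	TRUE	5	5	5	6	5
CC-NB	FALSE	3	3	4	0	2
CC-LRR	FALSE	0	0	2	2	0
TIR-NB	FALSE	1	3	5	3	5
TIR-LRR	FALSE	0	0	0	1	0
NB	FALSE	1	5	4	2	4
TIR	FALSE	6	10	9	5	10
LRR	FALSE	2	7	15	14	4
RPW8	FALSE	2	1	1	2	2
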