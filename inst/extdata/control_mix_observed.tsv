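mix	species	its_observed	shotgun_observed	its_ratio_printed	shotgun_ratio_printed
1	Saccharomyces cerevisiae	1e6	1e6	1	1
1	Metschnikowia pulcherrima	1.9e5	8.8e3	18.6	0.9
1	Torulaspora delbrueckii	7.3e5	4.8e5	0.7	0.5
1	Debaryomyces hansenii	8.4e6	2.9e6	0.8	0.3
1	Saccharomyces uvarum	5.7e2	1.8e3	0.6	1.8
1	Hanseniaspora uvarum	1.1e8	1.3e8	1.1	1.3
2	Saccharomyces cerevisiae	2e8	2e8	1	1
2	Metschnikowia pulcherrima	1.1e7	6.5e5	10.5	0.7
2	Torulaspora delbrueckii	6.6e4	4.7e4	0.7	0.5
2	Debaryomyces hansenii	2.4e3	0	2.4	0
2	Saccharomyces uvarum	7.9e4	1.1e5	0.8	1.1
2	Hanseniaspora uvarum	6.1e4	4.4e4	6.1	4.4
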