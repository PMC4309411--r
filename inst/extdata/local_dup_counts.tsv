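chromosome	dup_hr	dup_lr	all_hr	all_lr
1H	702	150	3405	895
2H	937	200	4183	1398
3H	1055	229	4172	1384
4H	480	169	2421	1226
5H	1120	168	4711	1148
6H	676	217	2820	1487
7H	1112	164	4733	1150
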