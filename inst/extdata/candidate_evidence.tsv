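sequence	modification	missed_cleavages	is_unique	mean_abundance	det_2	det_5	det_10	det_15	det_20	det_25
APKLLIYDTSKLASGVPSR	acetylation	2	TRUE	120000	0	0	0	0	4	4
DIQMTQSPSTLSASVGDR		0	FALSE	350000	0	3	4	4	4	4
LLIYDTSKLASGVPSR		1	TRUE	200000	0	0	0	3	4	4
LLIYDTSK		0	TRUE	840000	4	4	4	4	4	4
LASGVPSR		0	TRUE	60000	0	1	1	3	2	2
VTNMDPADTATYYCAR	carbamidomethyl	0	TRUE	510000	4	4	4	4	4	4
LTISKDTSKNQVVLK		2	TRUE	90000	0	0	0	2	4	3
KDYNPSLK	acetylation	1	TRUE	260000	0	3	4	4	4	4
SRLTISK	phosphorylation	1	FALSE	180000	0	0	4	4	4	4
NQVVLK		0	FALSE	220000	0	0	2	4	4	4
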