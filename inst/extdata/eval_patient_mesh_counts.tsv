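case	diagnosis	n_pred_ibc	n_pred_dcis	ratio_ibc_printed	predicted_category_printed
IBC-1	IBC	157	4	0.975	IBC
IBC-2	IBC	1398	3	0.998	IBC
IBC-3	IBC	579	0	1.000	IBC
IBC-4	IBC	185	5	0.974	IBC
IBC-5	IBC	228	0	1.000	IBC
IBC-6	IBC	54	0	1.000	IBC
IBC-7	IBC	2111	1	0.995	IBC
DCIS-1	DCIS	6	138	0.042	DCIS
DCIS-2	DCIS	1	49	0.020	DCIS
DCIS-3	DCIS	0	98	0.000	DCIS
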