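condition	cell_type	n_cells	ttp_mean_ms	ttp_spread_ms
control_a	ON	240	67.36	12.06
control_a	OFF	955	48.60	8.13
control_b	ON	180	64.81	8.41
control_b	OFF	693	48.34	7.44
blocker	ON	23	94.9	19.3
blocker	OFF	77	61.5	12.1
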