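#oncohistone-screen v0.1.0
# Secondary-transplant engraftment (percent human CD45+ in the injected femur, 14 weeks)
mouse_id	group	percent_engraftment	cells_injected
H3H_WT_m1	HIST1H3H_WT	0.07	975000
H3H_WT_m2	HIST1H3H_WT	0.11	975000
H3H_WT_m3	HIST1H3H_WT	0.09	975000
H3H_K27M_m1	HIST1H3H_K27M	24.7	975000
H3H_K27M_m2	HIST1H3H_K27M	30.9	975000
H3H_K27M_m3	HIST1H3H_K27M	74.3	975000
H3F_WT_m1	HIST1H3F_WT	0	852000
H3F_WT_m2	HIST1H3F_WT	3.1	852000
H3F_WT_m3	HIST1H3F_WT	0.43	852000
H3F_K27I_m1	HIST1H3F_K27I	24.7	852000
H3F_K27I_m2	HIST1H3F_K27I	1.66	852000
H3F_K27I_m3	HIST1H3F_K27I	22.8	852000
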