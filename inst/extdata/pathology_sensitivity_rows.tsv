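group	parameter	lo_frac	hi_frac	min_effect_pct	max_effect_pct	reported_effect_size
glycine_interaction	ec50_inhibitory	-0.50	0.50	-18.6	20.7	0.393
glycine_interaction	hill_slope_inhibitory	-0.50	0.50	-22.1	13.4	0.355
glycine_interaction	ec50_excitatory	-0.50	0.50	-14.1	38.9	0.530
glycine_interaction	hill_slope_excitatory	-0.50	0.50	-18.4	14.3	0.327
cortical_pathology	nmda_reduction	-0.20	0.20	-37.7	18.2	1.398
cortical_pathology	gaba_reduction	-0.10	0.10	-32.4	20.8	1.620
cortical_pathology	da_deficit	-0.41	0.41	-7.9	2.8	0.130
cortical_pathology	noise_increase	-0.24	0.24	-13.9	18.5	0.675
striatal_physiology	da_receptors	-0.20	0.20	-9.3	10.1	0.485
striatal_physiology	muscarinic_receptors	-0.20	0.20	-3.5	15.6	0.478
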