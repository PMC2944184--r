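statistic	value	oracle
gamma3_gamma	-0.346410161513775	direct formula arithmetic (T = 5, S_2 = 2)
harmonic_n10_gamma	0	algebraic identity: harmonic intervals give gamma = 0
study_pruned_n_branching_times	89	n - 1 for a binary 90-tip tree
study_complete_root_age	16.2	rescaled to 16.2 by construction
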