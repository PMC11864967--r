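hypothesis	mean_n_segments	sd_n_segments	n_rep	min_len_cM	map_total_cM
avuncular	46.944	4.63376818747231	500	8	3400
grandparent_grandchild	37.178	5.1078857655578	500	8	3400
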