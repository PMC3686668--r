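dataset	n_pos	n_neg	imbalance_printed
human	1406	81228	57.8
arabidopsis	231	28359	122.8
animal	7053	218154	30.9
plant	2172	114929	52.9
virus	237	839	3.5
microPred	691	9248	13.4
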