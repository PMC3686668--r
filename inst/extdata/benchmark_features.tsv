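dataset	se	sp	gm
human	95.31	97.18	96.24
arabidopsis	96.11	99.31	97.70
animal	94.92	96.60	95.76
plant	92.36	98.38	95.32
virus	96.18	95.95	96.06
microPred	92.76	96.46	94.59
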