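dataset	classifier	variant	se	sp	gm
human	naive_bayes	III	87.98	96.33	92.06
human	naive_bayes	IV	91.97	93.93	92.94
human	perceptron	III	69.56	99.84	83.34
human	perceptron	IV	94.17	94.99	94.58
human	svm	III	69.56	99.85	83.34
human	svm	IV	92.53	95.69	94.10
human	random_forest	III	68.21	99.85	82.53
human	random_forest	IV	91.53	96.34	93.90
human	aplsc	III	94.88	92.14	93.50
human	smote_svm	III	77.67	99.02	87.69
arabidopsis	naive_bayes	III	86.99	98.91	92.76
arabidopsis	naive_bayes	IV	91.30	97.77	94.48
arabidopsis	perceptron	III	80.09	99.95	89.47
arabidopsis	perceptron	IV	93.04	97.47	95.23
arabidopsis	svm	III	80.07	99.96	89.47
arabidopsis	svm	IV	93.04	98.95	95.95
arabidopsis	random_forest	III	83.55	99.94	91.38
arabidopsis	random_forest	IV	95.22	99.04	97.11
arabidopsis	aplsc	III	96.09	90.42	93.21
arabidopsis	smote_svm	III	88.71	99.64	94.02
animal	naive_bayes	III	85.54	95.53	90.40
animal	naive_bayes	IV	88.83	92.81	90.79
animal	perceptron	III	74.03	99.65	85.89
animal	perceptron	IV	91.78	95.13	93.44
animal	svm	III	72.04	99.74	84.77
animal	svm	IV	90.67	90.09	93.34
animal	random_forest	III	72.52	99.72	85.04
animal	random_forest	IV	92.00	95.21	93.59
animal	aplsc	III	91.93	91.13	91.53
animal	smote_svm	III	84.56	98.68	91.35
plant	naive_bayes	III	83.56	97.56	90.29
plant	naive_bayes	IV	87.48	95.84	91.57
plant	perceptron	III	77.30	99.80	87.83
plant	perceptron	IV	89.64	97.38	93.43
plant	svm	III	73.07	99.85	85.42
plant	svm	IV	89.46	97.93	93.60
plant	random_forest	III	78.41	99.81	88.47
plant	random_forest	IV	90.65	97.96	94.24
plant	aplsc	III	92.77	89.39	91.07
plant	smote_svm	III	81.31	99.32	89.86
virus	naive_bayes	III	93.21	93.21	93.21
virus	naive_bayes	IV	95.74	92.37	94.04
virus	perceptron	III	87.77	98.10	92.79
virus	perceptron	IV	94.08	95.71	94.89
virus	svm	III	90.31	98.10	94.12
virus	svm	IV	95.38	95.35	95.37
virus	random_forest	III	88.59	98.45	93.39
virus	random_forest	IV	93.26	96.31	94.77
virus	aplsc	III	96.61	92.97	94.77
virus	smote_svm	III	91.99	97.14	94.53
microPred	naive_bayes	III	80.32	94.27	87.02
microPred	naive_bayes	IV	89.43	87.91	88.67
microPred	perceptron	III	82.35	99.37	90.46
microPred	perceptron	IV	90.74	94.65	92.67
microPred	svm	III	79.31	99.72	88.93
microPred	svm	IV	89.29	97.01	93.07
microPred	random_forest	III	75.83	99.66	86.94
microPred	random_forest	IV	91.89	96.36	94.10
microPred	aplsc	III	91.45	90.96	91.21
microPred	smote_svm	III	87.70	98.83	93.10
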