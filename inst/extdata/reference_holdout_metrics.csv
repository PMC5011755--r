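run,method,accuracy,sensitivity,specificity
1,pca-svm,80.30,81.81,79.54
2,pca-svm,86.36,85.71,86.84
3,pca-svm,81.81,75.00,85.71
4,pca-svm,83.33,92.30,77.50
5,pca-svm,78.78,75.86,81.08
6,pca-svm,84.84,78.12,91.17
7,pca-svm,86.36,87.50,85.71
8,pca-svm,86.36,88.00,85.36
9,pca-svm,83.33,86.66,80.55
10,pca-svm,81.81,76.00,85.36
1,ppca-svm,87.87,87.50,88.09
2,ppca-svm,89.39,88.88,89.74
3,ppca-svm,86.36,93.33,80.55
4,ppca-svm,90.90,90.62,91.17
5,ppca-svm,89.39,92.59,87.18
6,ppca-svm,93.93,96.55,91.89
7,ppca-svm,89.39,96.00,85.36
8,ppca-svm,92.42,88.88,94.87
9,ppca-svm,92.42,95.45,90.90
10,ppca-svm,93.93,100,90.00
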