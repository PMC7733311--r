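grid_id,classifier,selector,n_features,picture,Z0,Z1,Z2,Z3
svm_mlp_t10,svm-sigmoid,t_statistic,10,P1,0.75,0.89,0.64,0.67
svm_mlp_t10,svm-sigmoid,t_statistic,10,P2,0.51,0.77,0.67,0.62
svm_mlp_t10,svm-sigmoid,t_statistic,10,P3,0.57,0.54,0.74,0.71
svm_mlp_t10,svm-sigmoid,t_statistic,10,P4,0.65,0.54,0.84,0.62
svm_mlp_t10,svm-sigmoid,t_statistic,10,P5,0.73,0.73,0.78,0.63
knn3_t10,3-nn,t_statistic,10,P1,0.75,0.75,0.78,0.81
knn3_t10,3-nn,t_statistic,10,P2,0.54,0.56,0.59,0.59
knn3_t10,3-nn,t_statistic,10,P3,0.34,0.6,0.6,0.6
knn3_t10,3-nn,t_statistic,10,P4,0.68,0.65,0.62,0.65
knn3_t10,3-nn,t_statistic,10,P5,0.65,0.55,0.58,0.55
svm_linear_t10,svm-linear,t_statistic,10,P1,0.72,0.75,0.75,0.81
svm_linear_t10,svm-linear,t_statistic,10,P2,0.69,0.77,0.64,0.56
svm_linear_t10,svm-linear,t_statistic,10,P3,0.69,0.69,0.57,0.6
svm_linear_t10,svm-linear,t_statistic,10,P4,0.78,0.65,0.68,0.7
svm_linear_t10,svm-linear,t_statistic,10,P5,0.7,0.7,0.73,0.68
svm_rbf_t10,svm-rbf,t_statistic,10,P1,0.58,0.53,0.64,0.67
svm_rbf_t10,svm-rbf,t_statistic,10,P2,0.62,0.64,0.44,0.49
svm_rbf_t10,svm-rbf,t_statistic,10,P3,0.57,0.66,0.54,0.51
svm_rbf_t10,svm-rbf,t_statistic,10,P4,0.62,0.65,0.59,0.62
svm_rbf_t10,svm-rbf,t_statistic,10,P5,0.6,0.5,0.55,0.6
svm_mlp_t5,svm-sigmoid,t_statistic,5,P1,0.67,0.86,0.64,0.89
svm_mlp_t5,svm-sigmoid,t_statistic,5,P2,0.51,0.46,0.51,0.77
svm_mlp_t5,svm-sigmoid,t_statistic,5,P3,0.63,0.63,0.69,0.51
svm_mlp_t5,svm-sigmoid,t_statistic,5,P4,0.57,0.57,0.7,0.81
svm_mlp_t5,svm-sigmoid,t_statistic,5,P5,0.75,0.55,0.6,0.65
svm_mlp_sfs3,svm-sigmoid,sfs,3,P1,0.72,0.78,0.83,0.89
svm_mlp_sfs3,svm-sigmoid,sfs,3,P2,0.72,0.74,0.59,0.69
svm_mlp_sfs3,svm-sigmoid,sfs,3,P3,0.83,0.77,0.71,0.57
svm_mlp_sfs3,svm-sigmoid,sfs,3,P4,0.7,0.76,0.76,0.62
svm_mlp_sfs3,svm-sigmoid,sfs,3,P5,0.83,0.65,0.7,0.8
svm_mlp_sfs5,svm-sigmoid,sfs,5,P1,0.75,0.89,0.92,0.81
svm_mlp_sfs5,svm-sigmoid,sfs,5,P2,0.72,0.51,0.79,0.72
svm_mlp_sfs5,svm-sigmoid,sfs,5,P3,0.69,0.8,0.6,0.69
svm_mlp_sfs5,svm-sigmoid,sfs,5,P4,0.62,0.65,0.76,0.81
svm_mlp_sfs5,svm-sigmoid,sfs,5,P5,0.73,0.78,0.73,0.78
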