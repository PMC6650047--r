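exercise,acc_all_features,acc_20_features,n_features_minimal,acc_minimal,kfold_mean,kfold_sd,kfold_lowest,sens_norm,sens_acl_op,sens_acl_no_op,binary_accuracy,true_norm_pct
SLCMJ,57,67,2,53,53,10,40,51,53,52,67,27
DLCMJ,73,82,4,73,62,13,57,68,72,72,78,43
SLDJ,66,68,2,56,56,11,45,50,64,53,69,39
DLDJ,82,87,3,81,77,8,67,75,84,85,83,52
SLHop,75,79,5,75,77,10,61,81,71,69,88,71
HuHo,67,74,5,69,74,10,57,74,71,63,83,70
CoDP,66,77,5,58,55,14,53,65,63,61,77,65
CoDU,66,67,2,52,63,10,39,53,56,48,70,40
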