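version: 1
description: 'Default detector selection: 91 configurations over 7 families, matching
  the published post-selection per-family counts; within-family membership is this
  package''s own representative choice.'
config_ids:
- LOF_k5_euclidean
- LOF_k5_manhattan
- LOF_k5_chebyshev
- LOF_k10_euclidean
- LOF_k10_manhattan
- LOF_k10_chebyshev
- LOF_k15_euclidean
- LOF_k15_manhattan
- LOF_k15_chebyshev
- LOF_k20_euclidean
- LOF_k20_manhattan
- LOF_k20_chebyshev
- LOF_k25_euclidean
- LOF_k25_manhattan
- LOF_k25_chebyshev
- KNN_k3_euclidean
- KNN_k5_euclidean
- KNN_k8_euclidean
- KNN_k10_euclidean
- KNN_k15_euclidean
- KNN_k20_euclidean
- KNN_k25_euclidean
- KNN_k30_euclidean
- KNN_k40_euclidean
- KNN_k50_euclidean
- AvgKNN_k3_euclidean
- AvgKNN_k3_manhattan
- AvgKNN_k5_euclidean
- AvgKNN_k5_manhattan
- AvgKNN_k8_euclidean
- AvgKNN_k8_manhattan
- AvgKNN_k10_euclidean
- AvgKNN_k10_manhattan
- AvgKNN_k15_euclidean
- AvgKNN_k15_manhattan
- AvgKNN_k20_euclidean
- AvgKNN_k20_manhattan
- AvgKNN_k25_euclidean
- AvgKNN_k30_euclidean
- AvgKNN_k40_euclidean
- AvgKNN_k50_euclidean
- CBLOF_c4_s1
- CBLOF_c4_s2
- CBLOF_c4_s3
- CBLOF_c6_s1
- CBLOF_c6_s2
- CBLOF_c6_s3
- CBLOF_c8_s1
- CBLOF_c8_s2
- CBLOF_c8_s3
- CBLOF_c10_s1
- CBLOF_c10_s2
- CBLOF_c10_s3
- CBLOF_c12_s1
- CBLOF_c12_s2
- CBLOF_c12_s3
- OCSVM_rbf_nu0.05
- OCSVM_rbf_nu0.1
- OCSVM_rbf_nu0.2
- OCSVM_rbf_nu0.3
- OCSVM_rbf_nu0.4
- FeatureBagging_e5_s1
- FeatureBagging_e5_s2
- FeatureBagging_e5_s3
- FeatureBagging_e5_s4
- FeatureBagging_e5_s5
- FeatureBagging_e10_s1
- FeatureBagging_e10_s2
- FeatureBagging_e10_s3
- FeatureBagging_e10_s4
- FeatureBagging_e10_s5
- FeatureBagging_e15_s1
- FeatureBagging_e15_s2
- FeatureBagging_e15_s3
- FeatureBagging_e15_s4
- FeatureBagging_e15_s5
- LSCP_p4_s1
- LSCP_p4_s2
- LSCP_p4_s3
- LSCP_p4_s4
- LSCP_p4_s5
- LSCP_p6_s1
- LSCP_p6_s2
- LSCP_p6_s3
- LSCP_p6_s4
- LSCP_p6_s5
- LSCP_p8_s1
- LSCP_p8_s2
- LSCP_p8_s3
- LSCP_p8_s4
- LSCP_p8_s5
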