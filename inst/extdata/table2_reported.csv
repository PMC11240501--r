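case_id,true_diagnosis,ratio_diffuse,ratio_anaplastic,ratio_gbm_tumor,ratio_gbm_necrosis,ratio_gbm_mvp,class_tau000,class_tau002,class_tau005
Case 13,diffuse astrocytoma,0.998,0.001,0,0.002,0,glioblastoma,diffuse astrocytoma,diffuse astrocytoma
Case 14,diffuse astrocytoma,0.722,0,0.074,0.201,0.003,glioblastoma,glioblastoma,glioblastoma
Case 15,anaplastic astrocytoma,0,0,1.000,0,0,glioblastoma,glioblastoma,glioblastoma
Case 17,diffuse astrocytoma,0.998,0,0,0.002,0,glioblastoma,diffuse astrocytoma,diffuse astrocytoma
Case 22,diffuse astrocytoma,0.994,0,0,0.002,0.004,glioblastoma,diffuse astrocytoma,diffuse astrocytoma
Case 25,diffuse astrocytoma,0.002,0.943,0.034,0.017,0.004,glioblastoma,glioblastoma,anaplastic astrocytoma
Case 27,anaplastic astrocytoma,0,0.113,0.887,0,0,glioblastoma,glioblastoma,glioblastoma
Case 29,anaplastic astrocytoma,0,0.477,0.521,0,0.002,glioblastoma,glioblastoma,glioblastoma
Case 38,diffuse astrocytoma,0.016,0,0,0.984,0,glioblastoma,glioblastoma,glioblastoma
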