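case_id,true_diagnosis,diffuse,anaplastic,gbm_tumor,gbm_necrosis,gbm_mvp
Case 13,diffuse astrocytoma,5025,3,0,9,0
Case 14,diffuse astrocytoma,216,0,22,60,1
Case 15,anaplastic astrocytoma,0,0,146,0,0
Case 17,diffuse astrocytoma,5280,0,0,9,0
Case 22,diffuse astrocytoma,530,0,0,1,2
Case 25,diffuse astrocytoma,1,449,16,8,2
Case 27,anaplastic astrocytoma,0,28,220,0,0
Case 29,anaplastic astrocytoma,0,296,323,0,1
Case 38,diffuse astrocytoma,6,0,0,367,0
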