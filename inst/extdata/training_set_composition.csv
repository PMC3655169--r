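diagnosis,class,n_cases,n_rois
Tuberculosis,benign,33,1150
Inflammatory pseudotumor,benign,27,808
Hamartoma,benign,30,812
Pulmonary interstitial edema,benign,1,189
Sclerosing hemangioma,benign,9,93
Clear cell tumor,benign,1,11
Chondroma,benign,5,68
Glandular cancer,malignant,155,5571
Squamous carcinoma,malignant,47,1125
Adenosquamous carcinoma,malignant,7,244
Malignant carcinoid tumor,malignant,2,37
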