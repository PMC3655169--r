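variable,level,benign,malignant
smoking,no,64,107
smoking,yes,42,105
sex,female,48,85
sex,male,58,127
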