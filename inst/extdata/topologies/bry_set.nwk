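(ALG,((HOR,(LIV,MOS)),(LYC,(FER,(GYM,ANG)))));
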