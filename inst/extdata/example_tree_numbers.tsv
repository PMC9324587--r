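neoplasms	C04
neoplasms by site	C04.588
digestive system neoplasms	C04.588.274
liver neoplasms	C04.588.274.623
hepatocellular carcinoma	C04.588.274.623.460
breast neoplasms	C04.588.180
respiratory tract diseases	C08
bronchial diseases	C08.127
asthma	C08.127.108
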