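entity	expressed	responsive
CREM	Yes	No
FOXP3	No	No
TCF7L2	Yes	No
SMAD3	No	No
PARP1	Yes	No
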