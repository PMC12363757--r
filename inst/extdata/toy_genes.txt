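# candidate genes functionally linked to LRRK2
GAK
DNAJC6
RAB29
SYNJ1
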