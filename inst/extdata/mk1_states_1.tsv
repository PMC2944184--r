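tip	state
t1	0
t2	0
t3	0
t4	0
t5	0
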