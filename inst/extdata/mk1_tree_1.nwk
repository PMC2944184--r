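((t1:1.82219249621823,t3:1.82219249621823):1.44183580568972,(t2:0.544972197127469,(t4:0.497756330271192,t5:0.497756330271192):0.047215866856277):2.71905610478047);
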