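(((t3:0.87329364936017,(t4:0.851174002118972,t5:0.851174002118972):0.0221196472411975):0.0341363042801563,(t1:0.225275917740045,t7:0.225275917740045):0.682154035900282):1.76811616894744,(t6:0.507267372876258,(t2:0.00439448439283296,t8:0.00439448439283296):0.502872888483425):2.16827874971151);
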