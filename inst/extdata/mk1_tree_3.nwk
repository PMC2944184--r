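((t3:0.239699563550909,(t1:0.21067948846933,t4:0.21067948846933):0.0290200750815794):0.0328269200399518,((t2:0.117753537980323,t6:0.117753537980323):0.00913509791716932,(t5:0.0304457404682834,t7:0.0304457404682834):0.0964428954292089):0.145637847693369);
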