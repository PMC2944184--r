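(t1:0.562086291471675,((t4:0.384822599915967,(t3:0.27650335766393,t5:0.27650335766393):0.108319242252037):0.0484354267828166,(t2:0.0340184904720761,t6:0.0340184904720761):0.399239536226707):0.128828264772892);
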