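((((Parus_major:0.35,Taeniopygia_guttata:0.35):0.25,Gallus_gallus:0.6):0.3,(Anolis_sagrei:0.7,(Poecilia_reticulata:0.5,Crocuta_crocuta:0.5):0.2):0.2):0.1,Outgroup_anemone:1.0);
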