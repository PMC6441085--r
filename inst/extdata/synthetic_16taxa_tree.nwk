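((Collembola_sex:0.30,Collembola_asex:0.28):0.05,((Zygentoma_sex:0.34,Zygentoma_asex:0.30):0.06,((Phasmatodea_sex:0.26,Phasmatodea_asex:0.28):0.06,((Mantodea_sex:0.28,Mantodea_asex:0.26):0.06,((Thysanoptera_sex:0.32,Thysanoptera_asex:0.30):0.06,((Sternorrhyncha_sex:0.30,Sternorrhyncha_asex:0.34):0.06,((Hymenoptera_sex:0.28,Hymenoptera_asex:0.30):0.06,(Psocodea_sex:0.26,Psocodea_asex:0.30):0.06):0.04):0.04):0.04):0.04):0.04):0.04,Remipedia_outgroup:0.55);
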