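species	mode	group	outgroup
Collembola_sex	sexual	Collembola	FALSE
Collembola_asex	asexual	Collembola	FALSE
Zygentoma_sex	sexual	Zygentoma	FALSE
Zygentoma_asex	asexual	Zygentoma	FALSE
Phasmatodea_sex	sexual	Phasmatodea	FALSE
Phasmatodea_asex	asexual	Phasmatodea	FALSE
Mantodea_sex	sexual	Mantodea	FALSE
Mantodea_asex	asexual	Mantodea	FALSE
Thysanoptera_sex	sexual	Thysanoptera	FALSE
Thysanoptera_asex	asexual	Thysanoptera	FALSE
Sternorrhyncha_sex	sexual	Sternorrhyncha	FALSE
Sternorrhyncha_asex	asexual	Sternorrhyncha	FALSE
Hymenoptera_sex	sexual	Hymenoptera	FALSE
Hymenoptera_asex	asexual	Hymenoptera	FALSE
Psocodea_sex	sexual	Psocodea	FALSE
Psocodea_asex	asexual	Psocodea	FALSE
Remipedia_outgroup	sexual	Remipedia	TRUE
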