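dataset,loss_km2,gain_km2
nbr,54019,207639
lc,151846,478040
vcf,65948,250919
gfc,61165,22405
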