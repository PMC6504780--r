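# SYNTHETIC coordinates: the published table prints no positions, so these
# place the five EXOC4-side SNPs inside the synthetic EXOC4 interval and the
# nine region-side SNPs inside the synthetic 1q23.1 interval (span 64 kb).
snp_id	chrom	pos_bp
rs10954428	7	1010000
rs12540206	7	1080000
rs6963221	7	1150000
rs7800006	7	1220000
rs6976491	7	1300000
rs1578761	1	2010000
rs975118	1	2018000
rs10489833	1	2026000
rs10797020	1	2034000
rs11264997	1	2042000
rs7512592	1	2050000
rs6679056	1	2058000
rs1873511	1	2066000
rs6697656	1	2074000
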