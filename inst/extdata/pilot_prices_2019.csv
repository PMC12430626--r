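market,price_cny_per_tco2e
Beijing,83.27
Shanghai,41.70
Guangdong,18.96
Shenzhen,10.84
Hubei,29.50
Tianjin,14.00
Chongqing,6.91
Fujian,16.89
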