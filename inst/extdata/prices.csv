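year,price
2017,2470
2018,1940
2019,3050
2020,3800
2021,5046
2022,4160
2023,3700
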