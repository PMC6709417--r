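country,non_ebf,ebf,total
South Africa,43,43,86
Thailand,72,42,114
Kenya,31,96,127
Sri Lanka,5,25,30
India,0,15,15
Guatemala,7,12,19
Ghana,19,8,27
Chile,6,22,28
Indonesia,4,115,119
All countries,187,378,565
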