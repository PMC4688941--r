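year,persons
1920,106021537
1930,123202624
1940,132164569
1950,151325798
1960,179323175
1970,203211926
1980,226545805
1990,248709873
2000,281421906
2010,308745538
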