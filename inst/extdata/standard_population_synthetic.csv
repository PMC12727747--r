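age_group,population
15-19,1550000
20-24,1700000
25-29,1850000
30-34,1950000
35-39,1850000
40-44,1700000
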