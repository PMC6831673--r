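language,n_2013,n_2014
English,18689,17032
Spanish,1707,1619
Vietnamese,54,348
Korean,147,156
Cantonese,68,115
Mandarin,58,219
Filipino/Tagalog,1,27
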