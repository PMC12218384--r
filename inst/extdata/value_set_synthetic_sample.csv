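state,utility
11111,1
21111,0.93
12345,0.2955
33333,0.3872
54321,0.255
55555,-0.532
11211,0.95
42513,0.3147
25152,0.2236
31415,0.3905
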