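r_t,b
0.1,53.064
0.5,65.478
1,81.1425
5,205.1310
10,360.350
50,1601.6
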