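id,peak_latency_ms
1,232
2,236
3,284
4,196
5,228
6,284
7,264
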