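g0013
g0016
g0017
g0029
g0044
g0054
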