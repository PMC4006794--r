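>hb_like_synthetic (synthetic A/T-rich zinc-finger-style matrix for examples and tests; not a database matrix)
A [ 20  2  1 22  1  1  1  1  8 12 ]
C [  2  1  2  1  1  1  1  1  6  4 ]
G [  2  2  1  1  1  1  1  1  6  4 ]
T [  2 21 22  2 23 23 23 23  6  6 ]
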