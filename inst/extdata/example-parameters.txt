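name charge sigma epsilon
CA 0.07 3.55 0.07
CB -0.18 3.50 0.066
N -0.47 3.30 0.17
O -0.51 2.96 0.21
P 1.50 3.80 0.585
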