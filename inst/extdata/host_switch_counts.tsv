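category	n_down	n_up
all	48	43
host_gain	15	4
host_loss	4	8
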