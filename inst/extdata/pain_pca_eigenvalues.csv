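component,eigenvalue
PC1,3.834
PC2,1.142
PC3,1.061
PC4,0.740
PC5,0.491
PC6,0.432
PC7,0.208
PC8,0.092
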