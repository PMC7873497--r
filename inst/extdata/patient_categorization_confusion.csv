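true_class,controls,glaucoma,neuro
controls,18,0,3
glaucoma,2,9,4
neuro,0,1,36
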