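F4 father 0 0 1 1
F4 mother 0 0 2 1
F4 proband father mother 1 2
F4 brother1 father mother 1 1
F4 brother2 father mother 1 1
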