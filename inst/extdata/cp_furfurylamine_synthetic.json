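{"coef":[20.10735437,0.3],"scale":1,"range":[250,400]}
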