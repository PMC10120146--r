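name,ps,peep,vt,f,pt
protective,24,10,0.38,22,25
moderate,27,8,0.45,18,23
high_drive,32,6,0.6,16,21
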