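site,pka
C1,11.3
C2,15.4
C3,15.5
C4,14.3
C6,17.3
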