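species,site,vie_eV
glucose0,HOMO,9.09
glucose0,HOMO-1,9.40
glucose0,HOMO-2,9.66
glucose-,HOMO,7.95
glucose-,HOMO-1,8.87
glucose-,HOMO-2,9.44
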