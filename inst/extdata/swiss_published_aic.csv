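family,municipal,refined
poisson,6449.3,6419.7
negbin,5930.2,5910.7
zip,6243.2,6223.5
zinb,5894.5,5878.2
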