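reference_id: synthetic_chicken_GSDMA
beta11_end: 230
alpha5_start: 255
alpha7p_alpha8_range:
- 314
- 347
nterm_range: ~
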