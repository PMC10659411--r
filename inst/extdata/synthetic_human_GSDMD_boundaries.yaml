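reference_id: synthetic_human_GSDMD
beta11_end: 260
alpha5_start: 290
alpha7p_alpha8_range:
- 347
- 380
nterm_range: ~
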