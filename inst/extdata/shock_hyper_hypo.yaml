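- t_min: 70
  c_e_mM: 500
- t_min: 100
  c_e_mM: 325
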