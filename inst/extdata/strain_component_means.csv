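group,eps_exc_iso_pct,eps_extr_pct
with_lenticels,12.6,28.1
without_lenticels,8.5,15.8
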