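metric,a_below_b_below,a_below_b_above,a_above_b_below,a_above_b_above
MTV,56,2,3,56
TLG,57,1,2,57
Dmax,49,10,9,49
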