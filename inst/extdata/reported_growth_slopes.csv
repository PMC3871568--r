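tumor_id,slope_per_day
mouse1,0.0057
mouse2,0.0182
mouse3A,0.0096
mouse3B,0.0297
mouse4A,0.0134
mouse4B,0.0195
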