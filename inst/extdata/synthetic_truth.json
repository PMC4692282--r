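{"generator":"parametric_sine","amplitude_cv":0.47,"period":41,"period_cv":0.11}
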