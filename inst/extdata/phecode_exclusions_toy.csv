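phecode,excluded_phecode
250.2,250.1
250.1,250.2
585,580
332,333
333,332
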