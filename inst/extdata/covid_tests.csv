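employment,positive,tested
Supermarket,0,352
Nursing home,3,444
Hospital,3,365
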