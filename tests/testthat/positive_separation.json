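{"separated":true,"gamma":[0,0,-1],"strict_rows":1}
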