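method	accuracy
MethodA	0.6
MethodB	0.7
MethodC	0.5
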