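target_id	method	go_id	confidence
toy	MethodA	GO1	0.5
toy	MethodA	GO2	0.6
toy	MethodA	GO3	0.4
toy	MethodB	GO2	0.7
toy	MethodB	GO3	0.8
toy	MethodB	GO4	0.4
toy	MethodB	GO5	0.6
toy	MethodC	GO2	0.8
toy	MethodC	GO3	0.9
toy	MethodC	GO5	0.6
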