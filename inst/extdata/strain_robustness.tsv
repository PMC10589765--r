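model	dpy_like	lon_like
default	0.995	0.814
generalist	0.995	0.968
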