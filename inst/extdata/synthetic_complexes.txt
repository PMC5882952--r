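1	p001 p002 p003 p004 p005 p006 p007 p008
2	p009 p010 p011 p012 p013 p014 p015 p016
3	p017 p018 p019 p020 p021 p022
4	p023 p024 p025
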