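GO:TRUE0001	p001
GO:TRUE0001	p002
GO:TRUE0001	p003
GO:TRUE0001	p004
GO:TRUE0001	p005
GO:TRUE0001	p006
GO:TRUE0001	p007
GO:TRUE0002	p009
GO:TRUE0002	p010
GO:TRUE0002	p011
GO:TRUE0002	p012
GO:TRUE0002	p014
GO:TRUE0002	p015
GO:TRUE0002	p016
GO:TRUE0003	p018
GO:TRUE0003	p019
GO:TRUE0003	p020
GO:TRUE0003	p021
GO:TRUE0003	p022
GO:TRUE0004	p023
GO:TRUE0004	p024
GO:TRUE0004	p025
GO:DECOY0001	p003
GO:DECOY0001	p009
GO:DECOY0001	p014
GO:DECOY0002	p016
GO:DECOY0002	p017
GO:DECOY0002	p020
GO:DECOY0003	p010
GO:DECOY0003	p011
GO:DECOY0003	p020
GO:DECOY0003	p023
GO:DECOY0003	p025
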