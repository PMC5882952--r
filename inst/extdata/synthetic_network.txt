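p001	p002
p001	p003
p001	p004
p001	p005
p001	p006
p001	p007
p001	p008
p002	p003
p002	p004
p002	p005
p002	p006
p002	p007
p002	p008
p002	p017
p003	p004
p003	p005
p003	p006
p003	p007
p003	p008
p003	p013
p004	p005
p004	p006
p004	p007
p004	p008
p004	p019
p005	p006
p005	p008
p006	p007
p006	p008
p006	p022
p007	p010
p007	p011
p007	p017
p008	p019
p009	p010
p009	p011
p009	p012
p009	p013
p009	p014
p009	p015
p009	p023
p010	p011
p010	p013
p010	p014
p010	p015
p010	p021
p010	p022
p011	p012
p011	p013
p011	p014
p012	p013
p012	p014
p012	p016
p013	p015
p013	p016
p014	p015
p015	p016
p016	p021
p017	p018
p017	p019
p017	p020
p017	p021
p018	p019
p018	p020
p018	p021
p018	p022
p019	p021
p019	p022
p020	p021
p021	p022
p023	p024
p024	p025
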