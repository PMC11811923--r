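pathway	label	kind	energy
(S)	substrate conformer	minimum	0.0
(S)	hemiaminal formation TS	transition_state	15.2
(S)	hemiaminal	minimum	2.0
(S)	dehydration TS	transition_state	10.7
(S)	iminium	minimum	-1.0
(R)	substrate conformer	minimum	0.0
(R)	hemiaminal formation TS	transition_state	11.0
(R)	hemiaminal	minimum	-1.0
(R)	dehydration TS	transition_state	18.4
(R)	iminium	minimum	-4.0
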