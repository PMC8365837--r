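subjectId	region	metric	auc
sub-001	CtxA_L	degree	58
sub-001	CtxA_R	degree	52
sub-001	CtxB_L	degree	113
sub-001	CtxB_R	degree	61
sub-001	Hub_L	degree	11
sub-001	Hub_R	degree	35
sub-002	CtxA_L	degree	24
sub-002	CtxA_R	degree	68
sub-002	CtxB_L	degree	31
sub-002	CtxB_R	degree	54
sub-002	Hub_L	degree	82
sub-002	Hub_R	degree	41
sub-003	CtxA_L	degree	41
sub-003	CtxA_R	degree	17
sub-003	CtxB_L	degree	66
sub-003	CtxB_R	degree	78
sub-003	Hub_L	degree	52
sub-003	Hub_R	degree	68
sub-004	CtxA_L	degree	59
sub-004	CtxA_R	degree	45
sub-004	CtxB_L	degree	58
sub-004	CtxB_R	degree	79
sub-004	Hub_L	degree	61
sub-004	Hub_R	degree	28
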