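region	CtxA_L	CtxA_R	CtxB_L	CtxB_R	Hub_L	Hub_R
CtxA_L	0	0	0.4564917187	0.5206587931	0	0.3051844938
CtxA_R	0	0	0.5682054329	0.1260575065	0.3420266754	0.03461794506
CtxB_L	0.4564917187	0.5682054329	0	0.4678002038	0.1517525173	0.4901947475
CtxB_R	0.5206587931	0.1260575065	0.4678002038	0	0.08964983448	0.2161486834
Hub_L	0	0.3420266754	0.1517525173	0.08964983448	0	0.07543225781
Hub_R	0.3051844938	0.03461794506	0.4901947475	0.2161486834	0.07543225781	0
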