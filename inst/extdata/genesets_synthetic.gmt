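RNA_SPLICING_AND_STABILITY	synthetic example set	HNRNPH1	HNRNPC	HNRNPD	HNRNPL	HNRNPU	HNRNPR	MBNL1	MBNL2
MITOCHONDRIAL_METABOLISM	synthetic example set	MRPS26	MRPL28	HCCS	VDAC3
CYTOSKELETON_AND_TRANSPORT	synthetic example set	KIF5B	DIAPH3
SYNTHETIC_PROCESS_A	synthetic example set	SYNT01	SYNT02	SYNT03	SYNT04	SYNT05	SYNT06	SYNT07	SYNT08	SYNT09	SYNT10
BACKGROUND_SET_A	synthetic example set	g0001	g0002	g0003	g0004	g0005	g0006	g0007	g0008	g0009	g0010	g0011	g0012	g0013	g0014	g0015	g0016	g0017	g0018	g0019	g0020	g0021	g0022	g0023	g0024	g0025	g0026	g0027	g0028	g0029	g0030
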