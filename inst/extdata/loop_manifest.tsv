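# CBTC loop manifest (reconstructed edge lists; see package docs)
loop	hemisphere	region_a	region_b
short	L	MPFC	CAU_MPFC
short	L	CAU_MPFC	THA_MPFC
short	L	THA_MPFC	MPFC
short	L	DLPFC	CAU_DLPFC
short	L	CAU_DLPFC	THA_DLPFC
short	L	THA_DLPFC	DLPFC
short	L	M1	CAU_M1
short	L	CAU_M1	THA_M1
short	L	THA_M1	M1
short	L	PMC	CAU_PMC
short	L	CAU_PMC	THA_PMC
short	L	THA_PMC	PMC
short	L	OFC	CAU_OFC
short	L	CAU_OFC	THA_OFC
short	L	THA_OFC	OFC
short	L	M1	PUT_M1
short	L	PUT_M1	THA_M1
short	L	DLPFC	PUT_DLPFC
short	L	PUT_DLPFC	THA_DLPFC
long	L	MPFC	CAU_MPFC
long	L	CAU_MPFC	PAL_MPFC
long	L	PAL_MPFC	THA_MPFC
long	L	THA_MPFC	MPFC
long	L	DLPFC	CAU_DLPFC
long	L	CAU_DLPFC	PAL_DLPFC
long	L	PAL_DLPFC	THA_DLPFC
long	L	THA_DLPFC	DLPFC
long	L	M1	CAU_M1
long	L	CAU_M1	PAL_M1
long	L	PAL_M1	THA_M1
long	L	THA_M1	M1
long	L	PMC	CAU_PMC
long	L	CAU_PMC	PAL_PMC
long	L	PAL_PMC	THA_PMC
long	L	THA_PMC	PMC
long	L	OFC	CAU_OFC
long	L	CAU_OFC	PAL_OFC
long	L	PAL_OFC	THA_OFC
long	L	M1	PUT_M1
long	L	PUT_M1	PAL_M1
atlas	L	MPFC	CAU
atlas	L	DLPFC	CAU
atlas	L	M1	CAU
atlas	L	PMC	CAU
atlas	L	OFC	CAU
atlas	L	MPFC	PUT
atlas	L	DLPFC	PUT
atlas	L	M1	PUT
atlas	L	PMC	PUT
atlas	L	OFC	PUT
atlas	L	MPFC	PAL
atlas	L	DLPFC	PAL
atlas	L	M1	PAL
atlas	L	PMC	PAL
atlas	L	OFC	PAL
atlas	L	MPFC	THA
atlas	L	DLPFC	THA
atlas	L	M1	THA
atlas	L	PMC	THA
atlas	L	OFC	THA
atlas	L	CAU	PUT
atlas	L	CAU	PAL
atlas	L	CAU	THA
atlas	L	PUT	PAL
atlas	L	PUT	THA
atlas	L	PAL	THA
short	R	MPFC	CAU_MPFC
short	R	CAU_MPFC	THA_MPFC
short	R	THA_MPFC	MPFC
short	R	DLPFC	CAU_DLPFC
short	R	CAU_DLPFC	THA_DLPFC
short	R	THA_DLPFC	DLPFC
short	R	M1	CAU_M1
short	R	CAU_M1	THA_M1
short	R	THA_M1	M1
short	R	PMC	CAU_PMC
short	R	CAU_PMC	THA_PMC
short	R	THA_PMC	PMC
short	R	OFC	CAU_OFC
short	R	CAU_OFC	THA_OFC
short	R	THA_OFC	OFC
short	R	M1	PUT_M1
short	R	PUT_M1	THA_M1
short	R	DLPFC	PUT_DLPFC
short	R	PUT_DLPFC	THA_DLPFC
long	R	MPFC	CAU_MPFC
long	R	CAU_MPFC	PAL_MPFC
long	R	PAL_MPFC	THA_MPFC
long	R	THA_MPFC	MPFC
long	R	DLPFC	CAU_DLPFC
long	R	CAU_DLPFC	PAL_DLPFC
long	R	PAL_DLPFC	THA_DLPFC
long	R	THA_DLPFC	DLPFC
long	R	M1	CAU_M1
long	R	CAU_M1	PAL_M1
long	R	PAL_M1	THA_M1
long	R	THA_M1	M1
long	R	PMC	CAU_PMC
long	R	CAU_PMC	PAL_PMC
long	R	PAL_PMC	THA_PMC
long	R	THA_PMC	PMC
long	R	OFC	CAU_OFC
long	R	CAU_OFC	PAL_OFC
long	R	PAL_OFC	THA_OFC
long	R	M1	PUT_M1
long	R	PUT_M1	PAL_M1
atlas	R	MPFC	CAU
atlas	R	DLPFC	CAU
atlas	R	M1	CAU
atlas	R	PMC	CAU
atlas	R	OFC	CAU
atlas	R	MPFC	PUT
atlas	R	DLPFC	PUT
atlas	R	M1	PUT
atlas	R	PMC	PUT
atlas	R	OFC	PUT
atlas	R	MPFC	PAL
atlas	R	DLPFC	PAL
atlas	R	M1	PAL
atlas	R	PMC	PAL
atlas	R	OFC	PAL
atlas	R	MPFC	THA
atlas	R	DLPFC	THA
atlas	R	M1	THA
atlas	R	PMC	THA
atlas	R	OFC	THA
atlas	R	CAU	PUT
atlas	R	CAU	PAL
atlas	R	CAU	THA
atlas	R	PUT	PAL
atlas	R	PUT	THA
atlas	R	PAL	THA
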