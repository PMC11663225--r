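core_all_four	synthetic stand-in; core genes as published	GADD45B	UBE4B
lineB_peaks_apoptosis	synthetic stand-in, printed size 8	BCL2L11	SYNB01	SYNB02	SYNB03	SYNB04	SYNB05	SYNB06	SYNB07
lineA_peaks_apoptosis	synthetic stand-in, printed size 21	SYNA01	SYNA02	SYNA03	SYNA04	SYNA05	SYNA06	SYNA07	SYNA08	SYNA09	SYNA10	SYNA11	SYNA12	SYNA13	SYNA14	SYNA15	SYNA16	SYNA17	SYNA18	SYNA19	SYNA20	SYNA21
lineA_lineB_apoptosis	synthetic stand-in, printed size 11	SYNC01	SYNC02	SYNC03	SYNC04	SYNC05	SYNC06	SYNC07	SYNC08	SYNC09	SYNC10	SYNC11
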