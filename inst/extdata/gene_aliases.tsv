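# alias table applied after mechanical normalization (uppercase, strip
# hyphens/spaces/dots, transliterate Greek); alias -> canonical
alias	canonical
PLCPG	PLCG
PLCGAMMA	PLCG
IFNGAMMA	IFNG
IFNGAMMAR	IFNGR
IFNGAMMAR1	IFNGR1
IFNALPHA	IFNA
IFNALPHAR1	IFNAR1
TBX21	TBET
CMAF	MAF
MAP3K8	COT
MAP3K14	NIK
PTPN6	SHP1
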