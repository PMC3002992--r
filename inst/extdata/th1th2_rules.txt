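# Th1/Th2 differentiation gene regulatory network, consensus curation.
# One rule per line: activators and (minus-prefixed) inhibitors -> target.
# A gene switches on iff at least one activator and no inhibitor is active.
# Genes never appearing as targets (ANTIGEN, CD80, CD86, IFN-a, IL-7,
# IL-12, IL-18, TNFSF4) are extracellular input nodes.
# This variant reads the damaged receptor symbol of the source table as the
# type-I interferon receptor chain IFN-aR1 (ligand IFN-a); see the package
# vignette. The literal transcription ships alongside.
IRF4, NFAT, MAF, GATA3 -> IL-13
IRF4, NFAT, MAF, GATA3 -> IL-5
IFN-gR, -GATA3, STAT1 -> TBET
IL-7R, TBET, STAT4, STAT1, IRAK -> IFN-g
STAT6 -> MAF
STAT6, -TBET -> GATA3
IL-7 -> IL-7R
IL-18, -IL-4R -> IL-18R
IL-18R -> IRAK
IFN-aR1, IFN-gR -> STAT1
IFN-a -> IFN-aR1
IFN-g -> IFN-gR
IL-4, -SOCS1 -> IL-4R
IRF4, NFAT, MAF, GATA3 -> IL-4
CD80 -> CTLA4
CTLA4 -> SHP1
CD45, CD4 -> LCK
TCR, CD3, -SHP1, LCK -> ZAP70
ZAP70 -> SLP76
LCK -> VAV1
CD28, VAV1, SLP76 -> ITK
ITK -> PLC-g
ANTIGEN -> CD4
ANTIGEN -> TCR
ANTIGEN -> CD3
ANTIGEN -> CD45
TNFSF4 -> TNFRSF4
-IFN-gR, TNFRSF4, IKBKB -> NFKB
STAT6, NFKB -> IRF4
CD28, TNFRSF4, PLC-g, IRF4 -> NFAT
CD28, ICOS -> PI3K
PI3K -> AKT1
AKT1 -> COT
COT -> NIK
NIK -> IKBKB
CD86 -> CD28
IL-4R, -SHP1, -SOCS1 -> JAK1
IL-4R -> JAK3
IFN-aR1, JAK1, JAK3 -> STAT6
IL-12R, IFN-aR1, -STAT6 -> STAT4
IFN-gR, STAT1, TBET -> SOCS1
IL-12 -> IL-12R
TNFSF4 -> ICOS
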