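# Gene pairs with literature-annotated counter-regulatory (inhibitory)
# relationships, in source order; labels as printed.
label1	label2
GATA3	TBET
SHP1	JAK1
IL-4R	IL18R
SOCS1	IL-4R
SOCS1	JAK3
STAT6	STAT4
IFN-g	IL-4
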