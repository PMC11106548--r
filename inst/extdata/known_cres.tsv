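# Known cis-regulatory element library: one motif per line, name<TAB>IUPAC.
# Only elements with a published concrete consensus are pre-populated.
# Elements listed by name only in the literature are left as commented
# placeholders below -- fill in a consensus to include them in scans.
GCC-box-long	AGCCGCC
GCC-box	GCCGCC
E-box-G-box	CACGTG
site-II	GGNCCCAC
TCP-site-II	TGGGC
AC-element	ACCWACC
E-box-variant-N	MCAGNCTGK
E-box-variant	MCAGCTGK
# RSRE	<fill in consensus>
# CM2	<fill in consensus>
# AP2-like	<fill in consensus>
# P-box	<fill in consensus>
# GRF	<fill in consensus>
# FAR1	<fill in consensus>
# VNS	<fill in consensus>
# CGCG-box	<fill in consensus>
# GATA-like	<fill in consensus>
# homeobox	<fill in consensus>
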