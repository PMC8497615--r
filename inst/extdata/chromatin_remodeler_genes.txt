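# Chromatin-remodeling gene families screened for cohort-wide mutation
# burden: MLL (KMT2), KDM, ARID, SMARC and HIST1 families plus PBRM1.
# One HUGO symbol per line; edit freely.
# MLL family (lysine methyltransferases)
KMT2A
KMT2B
KMT2C
KMT2D
KMT2E
# KDM family (lysine-specific demethylases)
KDM1A
KDM2A
KDM2B
KDM3A
KDM4A
KDM4B
KDM5A
KDM5B
KDM5C
KDM6A
KDM6B
# ARID family (AT-rich interactive domain)
ARID1A
ARID1B
ARID2
ARID3A
ARID4A
ARID4B
ARID5B
# SWI/SNF (SMARC) family
SMARCA1
SMARCA2
SMARCA4
SMARCA5
SMARCB1
SMARCC1
SMARCC2
SMARCD1
SMARCE1
# histone cluster 1 family
HIST1H1C
HIST1H1E
HIST1H2BD
HIST1H3B
HIST1H4E
# Polybromo 1
PBRM1
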