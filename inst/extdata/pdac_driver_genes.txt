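# Curated pancreatic ductal adenocarcinoma driver genes.
# One uppercase symbol per line; '#' starts a comment.
# Core recurrently mutated PDAC drivers observed in this pipeline's cohorts:
KRAS
TP53
CDKN2A
SMAD4
ARID1A
GNAS
KDM6A
RNF43
TGFBR2
# Consensus PDAC driver genes from large sequencing studies
# (chromatin modification, TGF-beta signalling, RNA maturation, DNA repair):
ARID2
ATM
BCORL1
BRAF
CTNNB1
KMT2C
KMT2D
MAP2K4
PIK3CA
RBM10
SF3B1
U2AF1
ACVR1B
ACVR2A
TGFBR1
MARK2
NF1
BRCA2
PALB2
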