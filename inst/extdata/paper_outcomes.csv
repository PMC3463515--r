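gene,category,pattern
CEP63,DISC1_INTERACTOR,hit_loss_r1
CEP170,DISC1_INTERACTOR,neg_r2
FEZ1,DISC1_INTERACTOR,hit_loss_r1
PDE4B,DISC1_INTERACTOR,hit_loss_r1
SYNE1,DISC1_INTERACTOR,hit_loss_r2
ABCA13,RARE_VARIANT,negative
ASPM,RARE_VARIANT,hit_loss_r1
CCDC18,RARE_VARIANT,hit_gain_r1
CHD1,RARE_VARIANT,negative
CHD3,RARE_VARIANT,negative
CHD4,RARE_VARIANT,hit_loss_r1
CHD5,RARE_VARIANT,hit_loss_r1
CHD7,RARE_VARIANT,hit_loss_r2
CNTN4,RARE_VARIANT,negative
CNTNAP2,RARE_VARIANT,negative
FOXP1,RARE_VARIANT,hit_gain_r1
GNB1L,RARE_VARIANT,hit_loss_r1
KATNAL2,RARE_VARIANT,hit_loss_r1
KIF17,RARE_VARIANT,negative
NRXN1,RARE_VARIANT,hit_loss_r1
TBX1,RARE_VARIANT,hit_loss_r2
ANK3,COMMON_VARIANT,hit_loss_r1
CACNA1C,COMMON_VARIANT,negative
CCDC68,COMMON_VARIANT,hit_loss_r1
CNNM2,COMMON_VARIANT,negative
CSMD1,COMMON_VARIANT,negative
HISTH2BJ,COMMON_VARIANT,negative
MIR137,COMMON_VARIANT,hit_gain_mimic
MMP16,COMMON_VARIANT,negative
NEK4,COMMON_VARIANT,hit_loss_r1
NRGN,COMMON_VARIANT,negative
NOTCH4,COMMON_VARIANT,hit_loss_r1
NT5C2,COMMON_VARIANT,hit_loss_r1
ODZ4,COMMON_VARIANT,negative
PGBD1,COMMON_VARIANT,negative
PRSS16,COMMON_VARIANT,negative
SDCCAG8,COMMON_VARIANT,hit_loss_r1
STT3A,COMMON_VARIANT,negative
TCF4,COMMON_VARIANT,hit_loss_r1
TRANK1,COMMON_VARIANT,hit_loss_r1
TRIM26,COMMON_VARIANT,negative
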