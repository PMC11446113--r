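group,count
total,1795
development,1184
test,611
malignant,1396
benign,399
clear_cell_rcc,1191
papillary_rcc,51
chromophobe_rcc,78
mit_translocation_rcc,32
other_malignant,16
unclassified_rcc,28
angiomyolipoma,307
oncocytoma,18
cyst,55
other_benign,19
male,1104
srl,1138
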