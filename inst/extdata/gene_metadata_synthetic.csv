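gene,chromosome,admet_class,drug
NAT2,8,phase II,amitriptyline
NAT2,8,phase II,citalopram
NAT2,8,phase II,isoniazid
TPMT,6,phase II,amitriptyline
TPMT,6,phase II,azathioprine
UGT1A5,2,phase II,irinotecan
CYP2D6,22,phase I,amitriptyline
CYP2D6,22,phase I,citalopram
CYP2D6,22,phase I,codeine
CYP2C19,10,phase I,citalopram
CYP2C19,10,phase I,clopidogrel
ABCB1,7,transporter,clopidogrel
ABCB1,7,transporter,simvastatin
SLCO1B1,12,transporter,simvastatin
VKORC1,16,modifier,warfarin
ASIC2,17,unknown,lithium
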