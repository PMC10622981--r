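drug_id,name,drug_class,known_nci_cotreatment
anastrozole,Anastrozole,AI,FALSE
letrozole,Letrozole,AI,FALSE
exemestane,Exemestane,AI,FALSE
tamoxifen,Tamoxifen,SERM,FALSE
toremifene,Toremifene,SERM,FALSE
fulvestrant,Fulvestrant,SERD,FALSE
palbociclib,Palbociclib,iCDK46,FALSE
ribociclib,Ribociclib,iCDK46,FALSE
abemaciclib,Abemaciclib,iCDK46,FALSE
capecitabine,Capecitabine,antineoplastic,FALSE
paclitaxel,Paclitaxel,antineoplastic,FALSE
trastuzumab,Trastuzumab,antineoplastic,FALSE
pembrolizumab,Pembrolizumab,immunotherapy,FALSE
atezolizumab,Atezolizumab,immunotherapy,FALSE
morphine,Morphine,other,TRUE
lorazepam,Lorazepam,other,TRUE
metformin,Metformin,other,FALSE
amlodipine,Amlodipine,other,FALSE
paracetamol,Paracetamol,other,FALSE
levothyroxine,Levothyroxine,other,FALSE
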