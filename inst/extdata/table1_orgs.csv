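country,who,price
CMR,PRESENT,PRESENT
ETH,PRESENT,PRESENT
KEN,PRESENT,PRESENT
RWA,PRESENT,PRESENT
UGA,PRESENT,PRESENT
TZA,PRESENT,PRESENT
IND,PRESENT,PRESENT
BDI,PRESENT,PRESENT
STP,PRESENT,PRESENT
SDN,PRESENT,PRESENT
CPV,PRESENT,PRESENT
GNQ,PRESENT,PRESENT
NGA,PRESENT,PRESENT
BRA,PRESENT,PRESENT
MEX,NO_CLAIM,PRESENT
ECU,NO_CLAIM,PRESENT
IDN,NO_CLAIM,PRESENT
COD,ABSENT,ABSENT
NER,PRESENT,NO_CLAIM
TCD,NO_CLAIM,PRESENT
MDG,PRESENT,NO_CLAIM
MOZ,NO_CLAIM,PRESENT
AGO,NO_CLAIM,PRESENT
SLV,NO_CLAIM,PRESENT
COL,NO_CLAIM,PRESENT
SUR,NO_CLAIM,PRESENT
GUF,NO_CLAIM,PRESENT
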