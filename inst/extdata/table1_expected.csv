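country,name,score,category
CMR,Cameroon,100,Consensus presence
ETH,Ethiopia,100,Consensus presence
KEN,Kenya,100,Consensus presence
RWA,Rwanda,100,Consensus presence
UGA,Uganda,100,Consensus presence
TZA,United Republic of Tanzania,100,Consensus presence
IND,India,93,Very strong evidence for presence
BDI,Burundi,73,Strong evidence for presence
STP,Sao Tome and Principe,67,Strong evidence for presence
SDN,Sudan,60,Strong evidence for presence
CPV,Cape Verde,60,Strong evidence for presence
GNQ,Equatorial Guinea,47,Moderate evidence for presence
NGA,Nigeria,47,Moderate evidence for presence
BRA,Brazil,40,Moderate evidence for presence
MEX,Mexico,27,Moderate evidence for presence
ECU,Ecuador,27,Moderate evidence for presence
IDN,Indonesia,27,Moderate evidence for presence
COD,Democratic Republic of Congo,7,Indeterminate
NER,Niger,0,Indeterminate
TCD,Chad,0,Indeterminate
MDG,Madagascar,0,Indeterminate
MOZ,Mozambique,0,Indeterminate
AGO,Angola,0,Indeterminate
SLV,El Salvador,0,Indeterminate
COL,Colombia,0,Indeterminate
SUR,Suriname,0,Indeterminate
GUF,French Guiana,0,Indeterminate
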