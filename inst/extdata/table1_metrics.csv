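country,haq,sdi,lf_endemic,leprosy_endemic,tu_endemic,continent
CMR,43.4,0.47,1,1,1,AFRICA
ETH,44.1,0.35,1,1,1,AFRICA
KEN,51.7,0.46,1,1,1,AFRICA
RWA,50.5,0.40,0,1,1,AFRICA
UGA,45.9,0.41,1,1,1,AFRICA
TZA,47.7,0.43,1,1,1,AFRICA
IND,44.8,0.60,1,1,0,ASIA
BDI,40.3,0.33,1,1,1,AFRICA
STP,58.9,0.52,1,0,0,AFRICA
SDN,53.6,0.50,1,1,1,AFRICA
CPV,66.4,0.59,0,1,0,AFRICA
GNQ,51.0,0.56,1,1,1,AFRICA
NGA,42.2,0.52,1,1,1,AFRICA
BRA,64.8,0.66,1,1,0,LATIN_AMERICA
MEX,66.3,0.68,0,1,0,LATIN_AMERICA
ECU,65.8,0.63,1,1,0,LATIN_AMERICA
IDN,53.8,0.64,1,1,1,ASIA
COD,39.7,0.33,1,1,1,AFRICA
NER,35.8,0.23,1,1,1,AFRICA
TCD,32.3,0.29,1,1,1,AFRICA
MDG,42.1,0.37,1,1,0,AFRICA
MOZ,42.5,0.35,1,1,1,AFRICA
AGO,40.1,0.44,1,1,1,AFRICA
SLV,64.0,0.61,0,0,0,LATIN_AMERICA
COL,69.5,0.66,1,1,0,LATIN_AMERICA
SUR,62.8,0.63,1,1,0,LATIN_AMERICA
GUF,74.0,0.70,1,1,0,LATIN_AMERICA
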