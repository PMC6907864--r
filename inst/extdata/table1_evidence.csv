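country,year,diagnostic,case_count,study_id,source_id,study_year
CMR,2015,SIME_ALGORITHM,2416,cmr_mapping_2015,cmr_natl,2015
ETH,2013,SIME_ALGORITHM,1537,eth_mapping_2013,eth_natl,2013
KEN,2017,SIME_ALGORITHM,208,ken_survey_2017,ken_west,2017
RWA,2018,SIME_ALGORITHM,1143,rwa_mapping_2018,rwa_natl,2018
UGA,2017,SIME_ALGORITHM,52,uga_survey_2017,uga_east,2017
TZA,2016,SIME_ALGORITHM,65,tza_survey_2016,tza_north,2016
IND,2011,CLINICAL_PLUS_ICT,24,ind_city_2011,ind_imphal,2011
IND,2018,UNSPECIFIED,12,ind_nagpur_2018,ind_nagpur,2018
BDI,1976,UNSPECIFIED,158,bdi_market_1976,bdi_market,1976
STP,1997,UNSPECIFIED,20,stp_survey_1997,stp_series,1997
SDN,1985,UNSPECIFIED,24,sdn_survey_1985,sdn_series,1985
CPV,1984,UNSPECIFIED,18,cpv_survey_1984,cpv_series,1984
GNQ,1988,UNSPECIFIED,8,gnq_survey_1988,gnq_series,1988
NGA,2015,UNSPECIFIED,1,nga_case_2015,nga_case,2015
BRA,1976,UNSPECIFIED,2,bra_monograph_1976,bra_saopaulo,1976
BRA,1993,UNSPECIFIED,1,bra_case_1993,bra_central,1993
MEX,1953,UNSPECIFIED,8,mex_report_1953,mex_series,1953
ECU,1952,UNSPECIFIED,10,ecu_report_1952,ecu_subtropical,1952
IDN,1980,UNSPECIFIED,9,idn_java_1980,idn_java,1980
COD,1939,UNSPECIFIED,12,cod_report_1939,cod_series,1939
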