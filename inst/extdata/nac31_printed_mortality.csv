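# Published per-city results for the 31 million-plus non-attainment cities
# (study year 2017), transcribed from the source study's results text:
# GEMM 5-COD attributable deaths (central and 95% CI) for all 31 cities,
# NCD+LRI attributable deaths and annual PM2.5 where printed (NA otherwise).
# City class: X (> 5 million) / Y (1-5 million); zone: five-region split.
city,state,class,zone,pm25_printed,cod5_central,cod5_low,cod5_high,ncd_lri_central,ncd_lri_low,ncd_lri_high
Delhi,DL,X,North,121,10221,9069,11280,12505,11094,13872
Mumbai,MH,X,West,NA,9214,7885,10466,9627,8494,10736
Kolkata,WB,X,East,68,8663,7252,9981,8918,7880,9932
Ahmedabad,GJ,X,West,67,5265,4560,5926,5501,4860,6127
Hyderabad,TG,X,South,48,5250,4544,5920,5482,4832,6120
Bangalore,KA,X,South,36,4437,3818,5031,4907,4319,5487
Pune,MH,X,West,NA,2188,1871,2490,NA,NA,NA
Jaipur,RJ,Y,North,NA,3588,2972,4155,4138,3664,4600
Lucknow,UP,Y,Central,109,2310,1938,2650,NA,NA,NA
Amritsar,PB,Y,North,NA,2154,1930,2634,NA,NA,NA
Nagpur,MH,Y,West,NA,2143,1835,2432,NA,NA,NA
Ludhiana,PB,Y,North,NA,1806,1620,1981,NA,NA,NA
Chandigarh,CH,Y,North,NA,1727,1469,1968,NA,NA,NA
Surat,GJ,Y,West,NA,1663,1434,1882,NA,NA,NA
Patna,BR,Y,East,131,1418,1213,1606,NA,NA,NA
Vishakhapatnam,AP,Y,South,NA,1360,1173,1538,NA,NA,NA
Kanpur,UP,Y,Central,138,1322,1113,1512,NA,NA,NA
Jodhpur,RJ,Y,North,NA,1263,1047,1462,NA,NA,NA
Indore,MP,Y,Central,NA,1250,1046,1443,NA,NA,NA
Guwahati,AS,Y,East,NA,1003,810,1184,NA,NA,NA
Hubli,KA,Y,South,NA,830,715,942,NA,NA,NA
Bhopal,MP,Y,Central,NA,702,587,811,NA,NA,NA
Ghaziabad,UP,Y,Central,194,650,549,741,NA,NA,NA
Raipur,CT,Y,Central,NA,562,460,659,NA,NA,NA
Dehradun,UK,Y,Central,147,468,397,532,NA,NA,NA
Dhanbad,JH,Y,East,NA,412,352,467,NA,NA,NA
Bhubaneswar,OD,Y,East,NA,351,283,415,NA,NA,NA
Jammu,JK,Y,North,NA,224,190,256,NA,NA,NA
BhilaiDurg,CT,Y,Central,NA,222,182,260,NA,NA,NA
Asansol,WB,Y,East,NA,172,144,199,NA,NA,NA
Vadodara,GJ,Y,West,NA,65,56,74,66,59,75
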