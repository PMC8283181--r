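block,category,total,fatal,nonfatal
gender,female,254,45,208
gender,male,380,71,309
gender,unknown or missing,71,7,63
age_group,<18,11,2,9
age_group,18-64,310,54,254
age_group,65-84,244,50,194
age_group,>=85,1,1,0
age_group,unknown or missing,139,16,123
report_year,2011,1,0,1
report_year,2012,0,0,0
report_year,2013,6,3,3
report_year,2014,5,2,3
report_year,2015,29,6,23
report_year,2016,77,7,70
report_year,2017,110,19,91
report_year,2018,201,38,163
report_year,2019,225,41,182
report_year,2020,51,7,44
region,Europe,261,48,211
region,America,224,28,196
region,Asia,201,45,156
region,Oceania,15,1,14
region,Africa,0,0,0
region,unknown or missing,4,1,3
indication,melanoma,61,11,50
indication,lung cancer,392,79,312
indication,hematological cancer and lymphoma,26,2,24
indication,gastrointestinal cancer,28,2,26
indication,head and neck cancer,14,2,12
indication,breast cancer,13,3,10
indication,tumors of female reproductive organs,23,2,20
indication,mesothelioma,10,1,9
indication,non-specified malignant neoplasm,19,2,17
indication,tumors of urinary system,55,12,43
indication,other indications,17,3,14
indication,unknown or missing,47,4,43
outcome,death,123,123,0
outcome,life-threatening,83,0,83
outcome,disability,5,0,5
outcome,hospitalization,317,0,317
outcome,other serious,175,0,175
outcome,unknown or missing,2,0,0
reporter,non-health-professional,150,34,116
reporter,health-professional,552,89,461
reporter,unknown or missing,3,0,3
tto_bin,0-30,184,50,134
tto_bin,31-60,69,12,57
tto_bin,61-90,42,13,29
tto_bin,91-180,55,7,48
tto_bin,>180,63,6,56
tto_bin,unknown or missing,292,35,256
regimen,ipilimumab,22,7,15
regimen,tremelimumab,0,0,0
regimen,pembrolizumab,185,41,144
regimen,nivolumab,307,48,259
regimen,cemiplimab,4,0,4
regimen,atezolizumab,73,13,59
regimen,avelumab,4,0,4
regimen,durvalumab,24,2,21
regimen,ipilimumab+nivolumab,79,12,67
regimen,ipilimumab+pembrolizumab,4,0,4
regimen,tremelimumab+durvalumab,3,0,3
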