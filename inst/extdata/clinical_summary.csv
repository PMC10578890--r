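variable,type,group,level,n,mean,sd,count
age,quantitative,F,,15,43.06,16.15,
age,quantitative,U,,6,46,23.12,
sedation_days,quantitative,F,,15,10,6,
sedation_days,quantitative,U,,6,8,7,
icu_stay_days,quantitative,F,,15,18,8,
icu_stay_days,quantitative,U,,6,15,12,
gender,categorical,F,female,,,,4
gender,categorical,F,male,,,,11
gender,categorical,U,female,,,,1
gender,categorical,U,male,,,,5
contusion,categorical,F,yes,,,,14
contusion,categorical,F,no,,,,1
contusion,categorical,U,yes,,,,6
contusion,categorical,U,no,,,,0
tsah,categorical,F,yes,,,,12
tsah,categorical,F,no,,,,3
tsah,categorical,U,yes,,,,0
tsah,categorical,U,no,,,,6
edh,categorical,F,yes,,,,5
edh,categorical,F,no,,,,10
edh,categorical,U,yes,,,,0
edh,categorical,U,no,,,,6
ivh,categorical,F,yes,,,,0
ivh,categorical,F,no,,,,15
ivh,categorical,U,yes,,,,1
ivh,categorical,U,no,,,,5
neurosurgery,categorical,F,yes,,,,3
neurosurgery,categorical,F,no,,,,12
neurosurgery,categorical,U,yes,,,,3
neurosurgery,categorical,U,no,,,,3
inm,categorical,F,yes,,,,10
inm,categorical,F,no,,,,5
inm,categorical,U,yes,,,,5
inm,categorical,U,no,,,,1
marshall,categorical,F,II,,,,10
marshall,categorical,F,III,,,,2
marshall,categorical,F,V,,,,1
marshall,categorical,F,VI,,,,2
marshall,categorical,U,II,,,,1
marshall,categorical,U,III,,,,3
marshall,categorical,U,V,,,,2
marshall,categorical,U,VI,,,,0
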