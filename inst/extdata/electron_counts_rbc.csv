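"cell_type","timepoint","dose_gy","n","mean_fraction","se_fraction","change_pct","sig"
"RBC","pre",5,3,1,0.02,,
"RBC","pre",7.5,3,1,0.02,,
"RBC","pre",7.7,3,1,0.02,,
"RBC","pre",10,3,1,0.02,,
"RBC","pre",15,3,1,0.02,,
"RBC","pre",20,3,1,0.02,,
"RBC","4h",5,3,1.22,0.04,22.1,"*"
"RBC","4h",7.5,3,1.15,0.02,15.3,""
"RBC","4h",7.7,3,0.93,0.02,-7,""
"RBC","4h",10,3,1.06,0.01,5.7,""
"RBC","4h",15,3,1.17,0.01,16.5,""
"RBC","4h",20,3,1.13,0.07,13,""
"RBC","d1",5,3,1.1,0.06,9.8,""
"RBC","d1",7.5,3,1.37,0.02,37.1,"***"
"RBC","d1",7.7,3,0.92,0.03,-7.6,""
"RBC","d1",10,3,1.26,0.08,26.4,"**"
"RBC","d1",15,3,1.11,0.05,11.1,""
"RBC","d1",20,3,1.14,0.06,14.2,""
"RBC","d7",5,3,1.08,0.03,8.3,""
"RBC","d7",7.5,3,1.36,0.01,36,"***"
"RBC","d7",7.7,3,0.92,0.04,-8,""
"RBC","d7",10,3,1.28,0.05,27.5,"**"
"RBC","d7",15,3,0.98,0.02,-2.1,""
"RBC","d7",20,3,1.21,0.03,20.5,""
"RBC","d14",5,3,1.14,0.05,13.5,""
"RBC","d14",7.5,3,1.21,0.04,20.5,"*"
"RBC","d14",7.7,3,0.9,0.05,-10.1,""
"RBC","d14",10,3,1.16,0.06,16.1,""
"RBC","d14",15,3,1.01,0,1,""
"RBC","d14",20,3,1.14,0.02,14.2,""
"RBC","d30",5,3,0.75,0.12,-25.4,"**"
"RBC","d30",7.5,3,1.1,0.02,10.4,""
"RBC","d30",7.7,3,0.9,0.02,-9.8,""
"RBC","d30",10,3,1.11,0.06,11.4,""
"RBC","d30",15,3,1.04,0.04,3.6,""
"RBC","d30",20,3,1.19,0.03,18.8,""
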