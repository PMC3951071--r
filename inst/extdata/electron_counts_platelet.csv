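"cell_type","timepoint","dose_gy","n","mean_fraction","se_fraction","change_pct","sig"
"platelet","pre",5,3,1,0.05,,
"platelet","pre",7.5,3,1,0.05,,
"platelet","pre",7.7,3,1,0.05,,
"platelet","pre",10,3,1,0.05,,
"platelet","pre",15,3,1,0.05,,
"platelet","pre",20,3,1,0.05,,
"platelet","4h",5,3,0.46,0.23,-54.2,"**"
"platelet","4h",7.5,3,1.1,0.1,9.9,""
"platelet","4h",7.7,3,1.34,0.03,34.4,"#"
"platelet","4h",10,3,1.14,0.13,14.1,""
"platelet","4h",15,3,1.27,0.04,26.6,""
"platelet","4h",20,3,1.13,0.1,13.4,""
"platelet","d1",5,3,1.23,0.09,23.1,""
"platelet","d1",7.5,3,1.05,0.05,5.4,""
"platelet","d1",7.7,3,1.22,0.03,21.9,""
"platelet","d1",10,3,1.02,0.07,2.1,""
"platelet","d1",15,3,0.79,0.02,-21.1,""
"platelet","d1",20,3,0.96,0.07,-4.1,""
"platelet","d7",5,3,1.06,0.28,5.8,""
"platelet","d7",7.5,3,0.71,0.06,-29.3,""
"platelet","d7",7.7,3,0.98,0.09,-2.1,""
"platelet","d7",10,3,0.81,0.17,-19.1,""
"platelet","d7",15,3,0.7,0.07,-29.9,""
"platelet","d7",20,3,0.76,0.09,-23.6,""
"platelet","d14",5,3,0.66,0.17,-34.4,""
"platelet","d14",7.5,3,0.55,0.06,-45.5,"*"
"platelet","d14",7.7,3,0.63,0.03,-37,"#"
"platelet","d14",10,3,0.69,0.08,-30.6,""
"platelet","d14",15,3,0.66,0.05,-33.9,""
"platelet","d14",20,3,0.48,0.21,-51.8,""
"platelet","d30",5,3,0.61,0.12,-39.4,""
"platelet","d30",7.5,3,1.09,0.1,9.1,""
"platelet","d30",7.7,3,1.15,0.15,15.4,""
"platelet","d30",10,3,0.94,0.12,-5.9,""
"platelet","d30",15,3,0.7,0.23,-29.9,""
"platelet","d30",20,3,1.05,0.03,4.9,""
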