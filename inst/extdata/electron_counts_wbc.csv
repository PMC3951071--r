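"cell_type","timepoint","dose_gy","n","mean_fraction","se_fraction","change_pct","sig"
"WBC","pre",5,3,1,0.05,,
"WBC","pre",7.5,3,1,0.05,,
"WBC","pre",7.7,3,1,0.05,,
"WBC","pre",10,3,1,0.05,,
"WBC","pre",15,3,1,0.05,,
"WBC","pre",20,3,1,0.05,,
"WBC","4h",5,3,0.83,0.05,-17.2,""
"WBC","4h",7.5,3,0.61,0.09,-39.3,""
"WBC","4h",7.7,3,0.8,0.1,-19.7,""
"WBC","4h",10,3,0.54,0.04,-46.3,"*"
"WBC","4h",15,3,0.76,0.02,-23.6,""
"WBC","4h",20,3,0.53,0.04,-46.9,"*"
"WBC","d1",5,3,0.96,0.18,-4.1,""
"WBC","d1",7.5,3,0.45,0.07,-54.9,""
"WBC","d1",7.7,3,0.59,0.03,-41.5,""
"WBC","d1",10,3,0.44,0,-56.2,"**"
"WBC","d1",15,3,0.58,0.14,-42,"#"
"WBC","d1",20,3,0.33,0.04,-66.6,"***"
"WBC","d7",5,3,0.85,0.04,-15,""
"WBC","d7",7.5,3,0.76,0.16,-24,""
"WBC","d7",7.7,3,0.6,0.06,-39.6,""
"WBC","d7",10,3,0.77,0.02,-22.7,""
"WBC","d7",15,3,0.56,0.06,-44.3,"*"
"WBC","d7",20,3,0.47,0.07,-53.3,"**"
"WBC","d14",5,3,1.18,0.02,17.5,""
"WBC","d14",7.5,3,1.01,0.32,1.4,""
"WBC","d14",7.7,3,1.02,0.04,1.5,""
"WBC","d14",10,3,0.79,0.05,-20.7,""
"WBC","d14",15,3,0.56,0.15,-44.0,"*"
"WBC","d14",20,3,0.59,0.07,-41.2,"#"
"WBC","d30",5,3,0.56,0.12,-44.1,""
"WBC","d30",7.5,3,1.07,0.15,7,""
"WBC","d30",7.7,3,0.75,0.11,-25.4,""
"WBC","d30",10,3,0.78,0.02,-21.8,""
"WBC","d30",15,3,0.65,0.05,-34.8,""
"WBC","d30",20,3,0.74,0.08,-26.2,""
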