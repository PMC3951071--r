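"cell_type","timepoint","dose_gy","n","mean_fraction","se_fraction","change_pct","sig"
"lymphocyte","pre",5,3,1,0.05,,
"lymphocyte","pre",7.5,3,1,0.05,,
"lymphocyte","pre",7.7,3,1,0.05,,
"lymphocyte","pre",10,3,1,0.05,,
"lymphocyte","pre",15,3,1,0.05,,
"lymphocyte","pre",20,3,1,0.05,,
"lymphocyte","4h",5,3,0.44,0.22,-55.7,"***"
"lymphocyte","4h",7.5,3,0.44,0.06,-55.7,"***"
"lymphocyte","4h",7.7,3,0.47,0.08,-53.2,"***"
"lymphocyte","4h",10,3,0.49,0.05,-51.3,"***"
"lymphocyte","4h",15,3,0.45,0.06,-54.7,"***"
"lymphocyte","4h",20,3,0.23,0.02,-76.7,"***"
"lymphocyte","d1",5,3,0.59,0.08,-41.1,"*"
"lymphocyte","d1",7.5,3,0.42,0.04,-58.4,"***"
"lymphocyte","d1",7.7,3,0.41,0.08,-59.2,"***"
"lymphocyte","d1",10,3,0.4,0.01,-60,"***"
"lymphocyte","d1",15,3,0.25,0.03,-74.6,"***"
"lymphocyte","d1",20,3,0.23,0.06,-77,"***"
"lymphocyte","d7",5,3,0.82,0.09,-17.8,""
"lymphocyte","d7",7.5,3,0.71,0.13,-28.9,"#"
"lymphocyte","d7",7.7,3,0.29,0.05,-71.3,"***"
"lymphocyte","d7",10,3,0.76,0.06,-23.9,""
"lymphocyte","d7",15,3,0.51,0.06,-48.7,"***"
"lymphocyte","d7",20,3,0.41,0.07,-59.5,"***"
"lymphocyte","d14",5,3,1.09,0.04,9.4,""
"lymphocyte","d14",7.5,3,0.65,0.1,-35.1,"*"
"lymphocyte","d14",7.7,3,0.77,0.07,-22.9,""
"lymphocyte","d14",10,3,0.77,0.11,-23.4,""
"lymphocyte","d14",15,3,0.63,0.02,-36.8,"**"
"lymphocyte","d14",20,3,0.46,0.04,-53.7,"***"
"lymphocyte","d30",5,3,0.69,0.03,-31.5,"#"
"lymphocyte","d30",7.5,3,0.8,0.14,-20,""
"lymphocyte","d30",7.7,3,0.89,0.14,-11.3,""
"lymphocyte","d30",10,3,0.69,0.07,-31.5,"*"
"lymphocyte","d30",15,3,0.79,0.04,-20.6,""
"lymphocyte","d30",20,3,0.61,0.08,-39.2,"**"
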