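"cell_type","timepoint","dose_gy","n","mean_fraction","se_fraction","change_pct","sig"
"monocyte","pre",5,3,1,0.08,,
"monocyte","pre",7.5,3,1,0.08,,
"monocyte","pre",7.7,3,1,0.08,,
"monocyte","pre",10,3,1,0.08,,
"monocyte","pre",15,3,1,0.08,,
"monocyte","pre",20,3,1,0.08,,
"monocyte","4h",5,3,0.49,0.09,-50.6,""
"monocyte","4h",7.5,3,0.45,0.06,-55.1,""
"monocyte","4h",7.7,3,0.55,0.1,-45.4,""
"monocyte","4h",10,3,0.34,0.09,-66.1,"*"
"monocyte","4h",15,3,0.35,0.01,-64.7,"#"
"monocyte","4h",20,3,0.26,0.07,-73.6,"*"
"monocyte","d1",5,3,0.67,0.15,-32.6,""
"monocyte","d1",7.5,3,0.44,0.13,-55.9,""
"monocyte","d1",7.7,3,0.54,0.13,-46.2,""
"monocyte","d1",10,3,0.42,0.08,-54,"#"
"monocyte","d1",15,3,0.48,0.15,-52.3,""
"monocyte","d1",20,3,0.29,0.08,-71.4,"*"
"monocyte","d7",5,3,1.03,0.06,3.2,""
"monocyte","d7",7.5,3,0.9,0.19,-10,""
"monocyte","d7",7.7,3,2.47,0.84,147.2,"***"
"monocyte","d7",10,3,0.62,0.02,-18.5,""
"monocyte","d7",15,3,1.27,0.32,27.1,""
"monocyte","d7",20,3,0.61,0.06,-38.7,""
"monocyte","d14",5,3,0.98,0.19,-2.3,""
"monocyte","d14",7.5,3,1.12,0.14,12,""
"monocyte","d14",7.7,3,0.84,0.23,-15.8,""
"monocyte","d14",10,3,0.77,0.2,-10.6,""
"monocyte","d14",15,3,0.75,0.09,-25.4,""
"monocyte","d14",20,3,0.56,0.16,-43.9,""
"monocyte","d30",5,3,0.44,0.05,-56.3,""
"monocyte","d30",7.5,3,1.62,0.68,62.1,""
"monocyte","d30",7.7,3,0.72,0.16,-28.1,""
"monocyte","d30",10,3,0.72,0.18,-0.6,""
"monocyte","d30",15,3,0.5,0.04,-49.7,""
"monocyte","d30",20,3,0.75,0.16,-24.9,""
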