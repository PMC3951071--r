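"cell_type","timepoint","dose_gy","n","mean_fraction","se_fraction","change_pct","sig"
"eosinophil","pre",5,3,1,0.13,,
"eosinophil","pre",7.5,3,1,0.13,,
"eosinophil","pre",7.7,3,1,0.13,,
"eosinophil","pre",10,3,1,0.13,,
"eosinophil","pre",15,3,1,0.13,,
"eosinophil","pre",20,3,1,0.13,,
"eosinophil","4h",5,3,2.21,0.23,121.4,"*"
"eosinophil","4h",7.5,3,0.67,0.11,-32.7,""
"eosinophil","4h",7.7,3,0.53,0.13,-46.9,""
"eosinophil","4h",10,3,0.36,0.12,-63.6,""
"eosinophil","4h",15,3,0.38,0.01,-61.8,""
"eosinophil","4h",20,3,0.45,0.03,-55.2,""
"eosinophil","d1",5,3,0.48,0.09,-52,""
"eosinophil","d1",7.5,3,0.83,0.32,-17.1,""
"eosinophil","d1",7.7,3,0.6,0.18,-40.3,""
"eosinophil","d1",10,3,0.7,0.23,-30.5,""
"eosinophil","d1",15,3,0.59,0.17,-41,""
"eosinophil","d1",20,3,0.47,0.13,-55.6,""
"eosinophil","d7",5,3,0.65,0.28,-35.2,""
"eosinophil","d7",7.5,3,0.31,0.04,-68.9,""
"eosinophil","d7",7.7,3,0.26,0.13,-74,""
"eosinophil","d7",10,3,0.68,0.21,-32.3,""
"eosinophil","d7",15,3,0.29,0.03,-70.8,""
"eosinophil","d7",20,3,0.31,0.05,-68.9,""
"eosinophil","d14",5,3,1.61,0.17,60.6,""
"eosinophil","d14",7.5,3,0.56,0.18,-43.9,""
"eosinophil","d14",7.7,3,0.7,0.16,-29.7,""
"eosinophil","d14",10,3,0.28,0.05,-71.6,""
"eosinophil","d14",15,3,0.23,0.01,-77.1,""
"eosinophil","d14",20,3,0.44,0.23,-55.9,""
"eosinophil","d30",5,3,0.55,0.12,-45.4,""
"eosinophil","d30",7.5,3,0.84,0.12,-16,""
"eosinophil","d30",7.7,3,0.63,0.19,-36.8,""
"eosinophil","d30",10,3,0.61,0.02,-38.6,""
"eosinophil","d30",15,3,1.18,0.27,18.2,""
"eosinophil","d30",20,3,1.39,0.13,39.2,""
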