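"cell_type","timepoint","dose_gy","n","mean_fraction","se_fraction","change_pct","sig"
"neutrophil","pre",5,3,1,0.1,,
"neutrophil","pre",7.5,3,1,0.1,,
"neutrophil","pre",7.7,3,1,0.1,,
"neutrophil","pre",10,3,1,0.1,,
"neutrophil","pre",15,3,1,0.1,,
"neutrophil","pre",20,3,1,0.1,,
"neutrophil","4h",5,3,1.19,0.08,19.3,""
"neutrophil","4h",7.5,3,0.72,0.11,-27.6,""
"neutrophil","4h",7.7,3,1.42,0.19,42.4,""
"neutrophil","4h",10,3,0.59,0.1,-40.7,""
"neutrophil","4h",15,3,1.37,0.16,36.5,""
"neutrophil","4h",20,3,0.76,0.07,-24.4,""
"neutrophil","d1",5,3,1.59,0.52,59.6,""
"neutrophil","d1",7.5,3,0.47,0.08,-53.4,""
"neutrophil","d1",7.7,3,0.86,0.06,-14.2,""
"neutrophil","d1",10,3,0.46,0.02,-54,""
"neutrophil","d1",15,3,1.1,0.33,9.7,""
"neutrophil","d1",20,3,0.42,0.06,-58.4,""
"neutrophil","d7",5,3,0.87,0.02,-13.4,""
"neutrophil","d7",7.5,3,0.84,0.21,-16.2,""
"neutrophil","d7",7.7,3,0.84,0.14,-16.1,""
"neutrophil","d7",10,3,0.82,0.04,-18.5,""
"neutrophil","d7",15,3,0.56,0.08,-43.6,""
"neutrophil","d7",20,3,0.54,0.07,-46.1,""
"neutrophil","d14",5,3,1.27,0.02,27.1,""
"neutrophil","d14",7.5,3,1.66,0.75,66.1,""
"neutrophil","d14",7.7,3,1.34,0.03,33.7,""
"neutrophil","d14",10,3,0.89,0.11,-10.6,""
"neutrophil","d14",15,3,0.46,0.02,-53.8,""
"neutrophil","d14",20,3,0.82,0.13,-17.8,""
"neutrophil","d30",5,3,0.52,0.14,-47.7,""
"neutrophil","d30",7.5,3,1.52,0.1,52,""
"neutrophil","d30",7.7,3,0.72,0.1,-28.1,""
"neutrophil","d30",10,3,0.99,0.06,-0.6,""
"neutrophil","d30",15,3,0.6,0.07,-40.5,""
"neutrophil","d30",20,3,1.01,0.07,1,""
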