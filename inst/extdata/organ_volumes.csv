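# Reference organ volumes (cm^3) used as calibration targets.
organ,TRM,TRW,ORNL
Brain,1353,1183,1370
Thyroid,13.9,9.14,19.9
Lungs,3212,2358,3380
Heart wall,270,216,303
Heart content,390,311,437
Stomach wall,74.2,47.0,152
Stomach content,122,77.3,250
Liver,1325,957,1830
Gall bladder,17.9,14.6,10.1
Kidneys,315,221,288
Pancreas,36.4,40.3,90.7
Spleen,149,122,176
UB wall,20.0,18.9,45.7
UB content,85.0,84.0,203
Testes,24.6,NA,37.6
Uterus,NA,99.2,76.0
Ovaries,NA,11.2,8.38
Bone,5808,5094,7221
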