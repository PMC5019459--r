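Organ,Density,H,C,N,O,Ca,Na,P,S,Cl,K
Brain,1.03,10.7,14.5,2.2,71.2,0,0.2,0.4,0.2,0.3,0.3
Eyes,1.03,9.6,19.5,5.7,64.6,0,0.1,0.1,0.3,0.1,0
Thyroid,1.05,10.4,11.9,2.4,74.5,0,0.2,0.1,0.1,0.2,0.1
Breasts,1.02,11.6,51.9,0,36.5,0,0,0,0,0,0
Lungs,0.26,10.3,10.5,3.1,74.9,0,0.2,0.2,0.3,0.3,0.2
Heart,1.03,10.4,13.9,2.9,71.8,0,0.1,0.2,0.2,0.2,0.3
Stomach,1.05,10.6,11.5,2.2,75.1,0,0.1,0.1,0.1,0.2,0.1
Liver,1.06,10.3,18.6,2.8,67.1,0,0.2,0.2,0.3,0.2,0.3
Kidneys,1.05,10.3,13.2,3.0,72.4,0.1,0.2,0.2,0.2,0.2,0.2
Pancreas,1.05,10.6,16.9,2.2,69.4,0,0.2,0.3,0.1,0.2,0.2
Spleen,1.06,10.3,11.3,3.2,74.1,0,0.1,0.3,0.2,0.2,0.3
Small intestine,1.04,10.6,11.5,2.2,75.1,0,0.1,0.1,0.1,0.2,0.1
Large intestine,1.04,10.6,11.5,2.2,75.1,0,0.1,0.1,0.1,0.2,0.1
Urinary bladder,1.04,10.5,9.6,2.6,76.1,0,0.2,0.2,0.2,0.3,0.3
Testes,1.04,10.6,9.9,2.0,76.6,0,0.2,0.1,0.2,0.2,0.2
Ovaries,1.05,10.5,9.3,2.4,76.8,0,0.2,0.2,0.2,0.2,0.2
Uterus,1.04,10.6,31.5,2.4,54.7,0,0.1,0.2,0.2,0.1,0.2
Skin,1.1,10,20.4,4.2,64.5,0,0.2,0.1,0.2,0.3,0.1
Bone,1.4,7.3,25.5,3.1,47.9,10.2,0.3,5.1,0.2,0.1,0.1
Muscle,1.05,10.2,14.3,3.4,71.0,0,0.1,0.2,0.3,0.1,0.4
Soft tissue,1.03,10.5,25.6,2.7,60.2,0,0.1,0.2,0.3,0.2,0.2
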