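# Liquid water photon coefficients from the standard public-domain
# compilation: total mass attenuation (coherent included) and mass
# energy-absorption coefficient, cm^2/g. Used to anchor the semi-empirical
# elemental cross-section model.
energy_MeV,mu_rho,mu_en_rho
0.010,5.329,4.944
0.015,1.673,1.374
0.020,0.8096,0.5503
0.030,0.3756,0.1557
0.040,0.2683,0.0695
0.050,0.2269,0.0422
0.060,0.2059,0.0319
0.080,0.1837,0.0262
0.100,0.1707,0.0256
0.150,0.1505,0.0277
0.200,0.1370,0.0297
0.300,0.1186,0.0319
0.400,0.1061,0.0328
0.500,0.0969,0.0330
0.600,0.0896,0.0329
0.800,0.0786,0.0321
1.000,0.0707,0.0310
1.250,0.0632,0.0297
1.500,0.0575,0.0283
2.000,0.0494,0.0260
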