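# Tc-99m emission scheme (standard compilation; photon lines with yield >= 1%,
# K X-rays merged). The electron row is the total non-penetrating energy per
# decay (conversion + Auger electrons).
kind,energy_MeV,yield
photon,0.140511,0.885
photon,0.0184,0.040
electron,0.0163,1.0
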