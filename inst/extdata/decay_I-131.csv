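# I-131 emission scheme (standard compilation; photon lines with yield >= 1%,
# X-ray lines merged at their intensity-weighted energy). The electron row is
# the total non-penetrating energy per decay (beta mean + conversion + Auger).
kind,energy_MeV,yield
photon,0.0298,0.040
photon,0.080185,0.0262
photon,0.284305,0.0612
photon,0.364489,0.815
photon,0.636989,0.0716
photon,0.722911,0.0177
electron,0.192,1.0
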