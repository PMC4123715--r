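# As ilt_like but with the pore transition enthalpy and entropy
# sign-flipped: the open state is enthalpically favoured and heating
# closes the channel (heat deactivation, Q10 < 1).
channel_name: v2_like
units:
  energy: kJ/mol
  entropy: kJ/(mol.K)
J: {dH: 88, dS: 0.32816, z: 5.1}
L: {dH: -418, dS: -1.34, z: 0}
D: 5
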