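# Two-state heat-activated pore transition with weak voltage dependence:
# large enthalpy and entropy changes place the midpoint temperature near
# 44 C at depolarized voltages, so heating opens the channel across a
# broad voltage range.
channel_name: trpv1_like
units:
  energy: kJ/mol
  entropy: kJ/(mol.K)
L: {dH: 510, dS: 1.58, z: 0.76}
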