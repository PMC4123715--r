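# Decoupled variant of shaker_like: coupling reduced to D = 5 and the
# voltage-sensor midpoint shifted depolarized (to -20 mV at 25 C), which
# unmasks the heat-sensitive pore transition.
channel_name: ilt_like
units:
  energy: kJ/mol
  entropy: kJ/(mol.K)
J: {dH: 88, dS: 0.32816, z: 5.1}
L: {dH: 418, dS: 1.34, z: 0}
D: 5
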