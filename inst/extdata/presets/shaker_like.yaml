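# Strongly coupled allosteric channel: a steep voltage sensor (z = 5.1 e0)
# obligatorily coupled (D = 1e4) to a heat-sensitive pore opening.  The
# sensor entropy is calibrated so the conductance-voltage midpoint sits at
# -54.2 mV at 24 C.
channel_name: shaker_like
units:
  energy: kJ/mol
  entropy: kJ/(mol.K)
J: {dH: 88, dS: 0.37384, z: 5.1}
L: {dH: 418, dS: 1.34, z: 0}
D: 10000
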