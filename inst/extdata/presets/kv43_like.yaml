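# Like kv21_like with a slightly hyperpolarized, steeper availability
# curve.
channel_name: kv43_like
units:
  energy: kJ/mol
  entropy: kJ/(mol.K)
J: {dH: 88, dS: 0.37384, z: 5.1}
L: {dH: 418, dS: 1.34, z: 0}
D: 20
csi: {v_half: -65, q: 4}
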