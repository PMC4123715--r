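# Partially decoupled channel (D = 20) carrying a closed-state
# inactivation availability curve that falls through the same voltage
# range in which activation rises.
channel_name: kv21_like
units:
  energy: kJ/mol
  entropy: kJ/(mol.K)
J: {dH: 88, dS: 0.37384, z: 5.1}
L: {dH: 418, dS: 1.34, z: 0}
D: 20
csi: {v_half: -55, q: 3.5}
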