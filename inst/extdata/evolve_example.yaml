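# Desk-scale evolution of the bias trait with the five-point quality set
scenario: fig3b
seed: 1
learning:
  T: 1500
evo:
  N: 240
  G: 200
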