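# Two learners with qualities 0 and 1 under the reference parameters
scenario: fig1
seed: 1
learning:
  T: 3000
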