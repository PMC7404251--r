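AprBp:
  signal:
  - 1
  - 29
  propeptide:
  - 30
  - 107
  mature:
  - 108
  - 381
GseBp:
  signal:
  - 1
  - 26
  propeptide:
  - 27
  - 88
  mature:
  - 89
  - 303

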