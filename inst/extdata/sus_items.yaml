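# System Usability Scale: 10 items on a 1-5 scale with alternating keying
# (odd items positively keyed, even items negatively keyed); Brooke
# composite = sum of item contributions * 2.5, on a 0-100 scale.
items:
  - {id: 1,  keying: positive}
  - {id: 2,  keying: negative}
  - {id: 3,  keying: positive}
  - {id: 4,  keying: negative}
  - {id: 5,  keying: positive}
  - {id: 6,  keying: negative}
  - {id: 7,  keying: positive}
  - {id: 8,  keying: negative}
  - {id: 9,  keying: positive}
  - {id: 10, keying: negative}
rating_range: [1, 5]
scale_factor: 2.5
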