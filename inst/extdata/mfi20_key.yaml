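# MFI-20 scoring key: item -> domain assignment and reverse-scoring flag.
# Domains: general_fatigue, physical_fatigue, reduced_activity,
# reduced_motivation, mental_fatigue (four items each).
# Positively phrased items (reversed: true) are rescored as 6 - response so
# that higher scores always indicate more fatigue.
items:
  - {item: 1,  domain: general_fatigue,    reversed: false}
  - {item: 2,  domain: physical_fatigue,   reversed: true}
  - {item: 3,  domain: reduced_activity,   reversed: false}
  - {item: 4,  domain: reduced_motivation, reversed: false}
  - {item: 5,  domain: general_fatigue,    reversed: true}
  - {item: 6,  domain: reduced_activity,   reversed: false}
  - {item: 7,  domain: mental_fatigue,     reversed: false}
  - {item: 8,  domain: physical_fatigue,   reversed: false}
  - {item: 9,  domain: reduced_motivation, reversed: true}
  - {item: 10, domain: reduced_activity,   reversed: true}
  - {item: 11, domain: mental_fatigue,     reversed: false}
  - {item: 12, domain: general_fatigue,    reversed: false}
  - {item: 13, domain: mental_fatigue,     reversed: true}
  - {item: 14, domain: physical_fatigue,   reversed: true}
  - {item: 15, domain: reduced_motivation, reversed: false}
  - {item: 16, domain: general_fatigue,    reversed: true}
  - {item: 17, domain: reduced_activity,   reversed: true}
  - {item: 18, domain: reduced_motivation, reversed: true}
  - {item: 19, domain: mental_fatigue,     reversed: true}
  - {item: 20, domain: physical_fatigue,   reversed: true}
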