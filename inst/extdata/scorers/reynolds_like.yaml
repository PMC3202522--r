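# Additive first-generation rule table (position preferences + composition).
# Positions index 1..19 along the sense target site, 5'->3'.
# GC window: 30-52% of 19 nt -> 6..9 G+C. The internal-hairpin criterion is
# implemented as absence of a self-complementary stretch of >= 5 nt, a
# deterministic proxy for a duplex-melting-temperature cutoff.
scorer_id: reynolds_like
generation: 1
type: rules
score_range: [-2, 10]
rules:
  - kind: composition_window
    window: [1, 19]
    bases: [G, C]
    min_count: 6
    max_count: 9
    weight: 1.0
  - kind: base_at_position
    positions: [15, 16, 17, 18, 19]
    bases: [A, U]
    weight: 1.0
  - kind: base_at_position
    positions: [19]
    bases: [A]
    weight: 1.0
  - kind: base_at_position
    positions: [3]
    bases: [A]
    weight: 1.0
  - kind: base_at_position
    positions: [10]
    bases: [U]
    weight: 1.0
  - kind: base_at_position
    positions: [19]
    bases: [G, C]
    weight: -1.0
  - kind: base_at_position
    positions: [13]
    bases: [G]
    weight: -1.0
  - kind: absence_of_stretch
    stretch: self_complementary
    min_len: 5
    weight: 1.0
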