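# Ordinal first-generation condition set. Classes are ordered worst to best
# (III < II < Ib < Ia); a site satisfying all conditions is class Ia and each
# unmet condition drops one class. A base_at_position condition requires all
# of its positions to match.
scorer_id: ui_tei_like
generation: 1
type: ordinal
classes: [III, II, Ib, Ia]
conditions:
  - kind: base_at_position
    positions: [1]
    bases: [G, C]
  - kind: base_at_position
    positions: [19]
    bases: [A, U]
  - kind: composition_window
    window: [13, 19]
    bases: [A, U]
    min_count: 4
    max_count: 7
  - kind: absence_of_stretch
    stretch: [G, C]
    min_len: 9
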