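# Acceptance windows for the multi-score intersection filter.
# First-generation windows are mean +/- 2 SD of the scores of high-efficacy
# (>= 90% inhibition) training siRNAs; the canonical published values are
# shipped verbatim as defaults (a few differ from recomputed mean +/- 2 SD by
# <= 0.1 because the published SDs are rounded). Scorers without a shipped
# engine (amarzguioui, katoh, hsieh, takasaki) keep their canonical windows
# here so user-supplied tables for them are filtered consistently.
first_generation:
  reynolds_like: {min: 1.9, max: 9.15}
  ui_tei_like: {min_class: Ib}
  amarzguioui: {min: -1.21, max: 5.3}
  katoh: {min: 42.03, max: 97.01}
  hsieh: {min: -1.11, max: 3.11}
  takasaki: {min: -10.22, max: 14.06}
second_generation:
  min_inhibition: 70
final_ranker:
  threshold: 93
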