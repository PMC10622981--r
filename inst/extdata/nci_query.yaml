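# Neurocognitive-impairment case query: named SMQ/HLGT groups resolved
# against the term dictionary. PTs flagged as diseases in the dictionary are
# always removed from the resolved set (symptom-level case definition);
# explicit PT-level additions/removals may be listed below.
included_groups:
  - dementia
  - mental impairment disorders
  - cognitive and attention disorders and disturbances
  - deliria
  - dementia and amnestic condition
  - disturbances in thinking and perception
included_pts: []
excluded_pts: []
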