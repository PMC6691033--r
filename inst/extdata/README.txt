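Synthetic placeholder tables
----------------------------
phoneme_inventory_synthetic.csv : 12 Dutch-style monophthongs with typical
  adult formant values (Hz) and conventional grapheme categories. These are
  plausible synthetic placeholders, NOT measured reference data; replace
  with a measured inventory for real analyses.
vowel_stimuli_synthetic.csv : 16 stimulus points spread through a plausible
  acoustic vowel space (Hz). Synthetic placeholders for a morphed
  cardinal-vowel continuum; replace with the measured stimulus formants of
  an actual experiment.
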