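# Default pipeline configuration.  Paths are resolved against the package's
# extdata directory when not absolute.
enzyme_rules: enzyme_rules.tsv
catalog: bioactivity_catalog.tsv
predicates: safety_predicates.tsv
screen_min_len: 2
screen_max_len: 4
abbott_ph: 6.5
gi_absorption:
  # Human-intestinal-absorption ("white") ellipse of the BOILED-Egg model in
  # (TPSA, WLOGP) space: centre, semi-axes, anticlockwise rotation in degrees.
  center_tpsa: 71.051
  center_wlogp: 2.292
  semi_axis_tpsa: 71.0405
  semi_axis_wlogp: 4.370
  rotation_deg: -1.031325
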