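# Example calibration override for forageweb::load_config().
# Any field of default_parameters() can be replaced verbatim; sections
# and keys must match the default structure, and the merged set is
# validated. This example raises the discount rate, strengthens the
# sardine price and shifts the Pelican diet slightly toward anchovy.
econ:
  delta: 0.07
  sardine:
    p_tilde: 0.18
pelican:
  Gamma_a: 0.35
  Gamma_s: 0.45
  Gamma_other: 0.2
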