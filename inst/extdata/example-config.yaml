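# Example pipeline configuration. Every key is optional; omitted keys use the
# package defaults (the reference morphology and published bin calibration).
seed: 0
morph:
  L_um: 12400
  w_um: 64
  r_um: 39
  c_um: 18.6
  k: 0.33
  ell_um: 200
angles:
  theta1: 90
  theta_pos: 15
  theta_neg: 35
beta_bounds: [1, 1000]
ratio_method: median   # or "bootstrap"
eq32_halfangle: false
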