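# Example channelfe configuration: a short demonstration run of the
# coarse GM + Redi scenario on a reduced grid.  Omitted keys take the
# package defaults (see ?run_config, ?forcing_params, ?eddy_params,
# ?eco_params).
grid:
  ny: 12
  nz: 30
run:
  scenario: gm_redi
  years_spinup: 3
  years_output: 2
  seed: 1
eddy:
  kappa_redi: 1000
ecosystem:
  K_Fe: 0.065
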