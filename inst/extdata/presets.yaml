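# Plasticity presets: thresholds theta_* in uM, rates gamma_* in 1/s.
#
# theta values of "fig2" are the printed two-spine values; everything else
# (all rate constants, the "fig3" thresholds) is calibrated to reproduce the
# qualitative homo-/heterosynaptic sign patterns of the two-spine and
# multi-spine experiments, since these quantities are not experimentally
# constrained.
fig2:
  theta_d: 2.0e-3
  theta_p: 4.0e-3
  gamma_p: 480.0
  gamma_d: 24.8
fig3:
  theta_d: 0.03
  theta_p: 0.2
  gamma_p: 28.0
  gamma_d: 0.4
fig4-grid:
  theta_d: 2.0e-3
  theta_p: 4.0e-3
  gamma_p: 0.1
  gamma_d: 2.5
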