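# Three-element flow-invasive stair-step separator at the nominal operating
# point: 200 um x 10 mm channel, water at 1 cm/s, MyOne-class beads,
# permalloy elements under a 0.5 T vertical bias.
channel: {height_um: 200, length_um: 10000}
elements:
  layout: stair_step
  count: 3
  width_um: 40
  height_um: 40
  rise_um: 40        # vertical center-to-center step a
  spacing_um: 120    # horizontal center-to-center pitch b
  x0_um: 1000
  Mes_A_per_m: 8.6e5
bias_A_per_m: 3.9e5
particle: {radius_um: 0.5, density_kg_per_m3: 1800, Msp_A_per_m: 4.3e4, chi_a: 1.4}
fluid: {viscosity_kg_per_m_s: 1.0e-3, density_kg_per_m3: 1000}
inlet: {u_avg_m_per_s: 0.01, n_streams: 100}
coupling: {mode: one, phi_percent: 0}
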