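# Synthetic ground truth emulating magic-angle TA of chlorophyll a in
# acetone after B-band (Soret) excitation. Four sequential compartments:
# ~110 fs B->Q transfer, a small-amplitude ~2 ps component, a ~9 ps cooling
# component, and the 5 ns excited-state lifetime (fixed in fits because a
# 100 ps window cannot constrain it). Species spectra are sums of Gaussians
# in the delta-A sign convention (GSB/SE negative, ESA positive); the B GSB
# sits at 430 nm (23256 cm-1), the Qy GSB/SE at 670 nm (14925 cm-1) and
# grows in with the 110 fs component.
fixture_version: 1
excitation_band: B
solvent: acetone
topology: sequential
lifetimes_fs: [110, 2000, 9000, 5.0e+6]
fixed: [false, false, false, true]
irf_fwhm_fs: 30
t0_fs: 0
axis: {from: 13800, to: 24800, points: 72}
delays: {early: {from: -200, to: 1000, by: 25}, late: {from: 1200, to: 100000, points: 32}}
species:
  - name: B_excited
    gaussians:
      - {center: 23256, sigma: 500, amplitude: -1.00}
      - {center: 18000, sigma: 900, amplitude: 0.25}
      - {center: 14925, sigma: 260, amplitude: -0.15}
  - name: Qy_hot
    gaussians:
      - {center: 23256, sigma: 500, amplitude: -0.55}
      - {center: 14925, sigma: 282, amplitude: -0.70}
      - {center: 17500, sigma: 800, amplitude: 0.18}
  - name: Qy_warm
    gaussians:
      - {center: 23256, sigma: 500, amplitude: -0.55}
      - {center: 14925, sigma: 245, amplitude: -0.84}
      - {center: 17500, sigma: 800, amplitude: 0.18}
  - name: Qy_relaxed
    gaussians:
      - {center: 23256, sigma: 500, amplitude: -0.55}
      - {center: 14925, sigma: 228, amplitude: -0.92}
      - {center: 17500, sigma: 800, amplitude: 0.18}
      - {center: 16000, sigma: 300, amplitude: -0.05}
      - {center: 17100, sigma: 300, amplitude: -0.04}
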