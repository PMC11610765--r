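# Biphasic heat-flow fixtures per solvent and excitation band.
# E_photon: B excitation at 430 nm (23256 cm-1), Q excitation at 660 nm
# (15152 cm-1); Qy 0-0 at 670 nm (14925 cm-1). tau_IVR ~ 1 ps and
# tau_VC in the 7-9 ps range, varying mildly with solvent. The effective
# heat capacity (83.3 cm-1/K) is a documented stand-in chosen so B-band
# excitation peaks about 100 K above the bath; it is shared by all entries.
fixture_version: 1
acetone_B:  {e_photon: 23256, e_00: 14925, tau_ivr: 1.0, tau_vc: 8.0, t_bath: 295, heat_capacity: 83.3}
acetone_Q:  {e_photon: 15152, e_00: 14925, tau_ivr: 1.0, tau_vc: 8.0, t_bath: 295, heat_capacity: 83.3}
ethanol_B:  {e_photon: 23256, e_00: 14925, tau_ivr: 1.1, tau_vc: 9.0, t_bath: 295, heat_capacity: 83.3}
ethanol_Q:  {e_photon: 15152, e_00: 14925, tau_ivr: 1.1, tau_vc: 9.0, t_bath: 295, heat_capacity: 83.3}
benzonitrile_B: {e_photon: 23256, e_00: 14925, tau_ivr: 0.9, tau_vc: 7.0, t_bath: 295, heat_capacity: 83.3}
benzonitrile_Q: {e_photon: 15152, e_00: 14925, tau_ivr: 0.9, tau_vc: 7.0, t_bath: 295, heat_capacity: 83.3}
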