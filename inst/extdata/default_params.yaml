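# spinekin default parameter set (the study conditions).
# Units: concentrations uM, volumes fL, times s, first-order rates 1/s,
# bimolecular rates 1/(M s). Fields flagged 'calibrated' in
# param_provenance() were set once against the reference peak of the
# no-competition model at 1.25 uM PP1; all others are measured or derived.

k_pCaM4: 0.96
k_pCaMpartial: 0.1
kcat_pp1: 11.5
KM_pp1: 11.0
pp1_koff_policy: equal_kcat
pp1_koff_factor: 1.0
KD_CaM4_la: 0.065
koff_CaM4_la: 6.6
koff_CaM4_ha: 9.0e-05
KD_CaM0_la: 1450.0
kon_CaM0: 3800.0
ha_ca_lock_factor: 1000.0
cam_ca_rate_table:
  site:
  - C1
  - C2
  - N1
  - N2
  kon:
  - 6800000.0
  - 6800000.0
  - 1.08e+08
  - 1.08e+08
  koff_free:
  - 68.0
  - 10.0
  - 4150.0
  - 800.0
conc_CaM_total: 30.0
n_holoenzymes: 60
conc_PP1: 1.25
ca_baseline: 0.1
V_spine: 0.016
V_psd: 0.002915
reservoir_diameter_um: 0.7
reservoir_length_um: 1.5
epochs: 2
bursts_per_epoch: 5
aps_per_burst: 5
burst_rate_hz: 5.0
ap_rate_hz: 50.0
t_start: 1.0
epoch2_onset: 5.0
p_release_init: 0.2
n_docked_init: 7
redock_rate: 0.2
fac_step: 0.35
fac_tau: 0.12
n_nmdar: 15
bap_delay: 0.01
coincidence_window: 0.02
nmdar_refractory: 0.0
p_open: 0.6
n_ca_per_opening: 90
pulse_tau: 0.005
tau_ca_clear: 0.004
ca_clear_KM: 0.02
k_cam_exchange: 8.0
trapping: no
competition: no
psd_localization: 'off'

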