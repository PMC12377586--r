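metabolic:
  k_cat_hxt: 0.434832
  K_M_hxt: 0.1
  k_cat_gly: 0.0768055
  k_cat_ferm: 10.2719
  k_cat_resp_pyr: 0.0521307
  k_cat_resp_etoh: 0.078094
  k_cat_gng: 0.134328
  k_cat_etoh_transport: 0.02536
  K_M_etoh: 0.3
  y_atp_gly: 2.0
  y_atp_resp_pyr: 13.0
  y_atp_resp_etoh: 11.0
  e_atp_aa: 5.0
  e_atp_gng: 2.0
  c_pyr_aa: 1.0
  atp_maintenance: 0.005
  k_trans: 0.0349036
  act_min: 0.529246
  K_act: 0.0090449
  hill_act: 1.68541
  phi_max: 0.45
  phi_other: 0.05
  chi_rna: 1.6
  rib_rna_aa: 15500.0
timers:
  T1a: 6.0
  T2: 9.0
  TB: 72.0
  TG1star: 13.0
  CV_timer: 0.15
  far1_ref: 2.6e+10
  theta_K2: 1.538
  theta_rho: -0.0287
  K2_ref: .na.real
  rho_ref: .na.real
  CV_far1: 0.0
  gamma_T: 1.0
  lambda_ref: .na.real
population:
  n_lines: 10
  target_cells: 5000
  horizon: 8000.0
  seed: 1
  CV_partition: 0.1
  CV_timer: .na.real
  dt: 0.5
  burn_in_doublings: 5.0
g1s:
  Whi5_total: 1.25
  SBF_total: 1.0
  k14: 2.0
  k_phos: 0.2011
  alpha_W: 0.008
  k_release: 10.0
  cln3_scale: 4.0e-09
  k_sbf_act: 0.5
  release_threshold: 0.5
  rebind_time: 3.0
  substeps: 4
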