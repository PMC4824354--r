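# Reference disk lane: 60 mm outer radius, five 7 mm Histopaque-1077
# gradient sections (A distal ... E) plus proximal sample section F,
# capillary valves of 1 mm x 7 mm footprint and 0.67 mm bonded channel
# height at each internal boundary. Units: mm, g/mL, mPa.s, degrees, N/m.
# Fluid defaults model diluted whole blood (literature-typical values).
schema_version: 1
fluid:
  surface_tension_n_m: 0.058
  contact_angle_deg: 110
  density_g_ml: 1.060
  viscosity_mpa_s: 1.8
protocol:
  plateau_rcf: 500
  accel_rcf_min: 500
  decel_rcf_min: 322
  plateau_s: 240
  reference_radius_mm: 60
lane:
  disk_radius_mm: 60
  valve:
    height_mm: 0.67
    width_mm: 7
  sections:
    - {label: F, medium: sample, r_proximal_mm: 18, r_distal_mm: 25, volume_ul: 12}
    - {label: E, medium_density_g_ml: 1.077, medium_viscosity_mpa_s: 1.5, r_proximal_mm: 25, r_distal_mm: 32, volume_ul: 12}
    - {label: D, medium_density_g_ml: 1.077, medium_viscosity_mpa_s: 1.5, r_proximal_mm: 32, r_distal_mm: 39, volume_ul: 12}
    - {label: C, medium_density_g_ml: 1.077, medium_viscosity_mpa_s: 1.5, r_proximal_mm: 39, r_distal_mm: 46, volume_ul: 12}
    - {label: B, medium_density_g_ml: 1.077, medium_viscosity_mpa_s: 1.5, r_proximal_mm: 46, r_distal_mm: 53, volume_ul: 12}
    - {label: A, medium_density_g_ml: 1.077, medium_viscosity_mpa_s: 1.5, r_proximal_mm: 53, r_distal_mm: 60, volume_ul: 12}
panel:
  - {name: Monocyte, density_g_ml: 1.072, radius_um: 6.75, agglutination_factor: 1}
  - {name: Lymphocyte, density_g_ml: 1.075, radius_um: 4.5, agglutination_factor: 1}
  - {name: Basophil, density_g_ml: 1.075, radius_um: 4.75, agglutination_factor: 1}
  - {name: Neutrophil, density_g_ml: 1.085, radius_um: 6.75, agglutination_factor: 1}
  - {name: Eosinophil, density_g_ml: 1.095, radius_um: 6.75, agglutination_factor: 1}
  - {name: RBC, density_g_ml: 1.098, radius_um: 2.63, agglutination_factor: 3}
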