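# Shared fixture builders: randomized-but-seeded physical instances used
# by the property-style tests.

# A lane holding a single uniform medium section, for closed-form vs
# numerical comparisons with no boundary effects.
single_section_lane <- function(medium_density, medium_viscosity,
                                r_proximal, r_distal) {
  lane_design(list(medium_section("X", medium_density, medium_viscosity,
                                  r_proximal, r_distal)),
              list(), disk_radius = r_distal)
}

# Random valve/fluid/column instance with a pinning (non-wetting) fluid.
random_burst_instance <- function() {
  list(
    valve = valve_geometry(height = runif(1, 0.1, 2),
                           width = runif(1, 1, 10)),
    fluid = fluid_sample(surface_tension = runif(1, 0.02, 0.08),
                         contact_angle = runif(1, 95, 140),
                         density = runif(1, 1.0, 1.2),
                         viscosity = runif(1, 1, 4)),
    r_proximal = rp <- runif(1, 10, 40),
    r_distal = rp + runif(1, 2, 20)
  )
}

# Random (cell, section, protocol) sedimentation instance that is always
# traversable (cell strictly denser than the medium).
random_sedimentation_instance <- function() {
  med <- runif(1, 1.00, 1.09)
  cell <- cell_species("probe",
                       density = med + runif(1, 0.005, 0.06),
                       radius = runif(1, 2, 8),
                       agglutination_factor = sample(c(1, 1, 2, 3), 1))
  rp <- runif(1, 15, 45)
  section <- medium_section("X", med, runif(1, 0.8, 3),
                            r_proximal = rp,
                            r_distal = rp + runif(1, 3, 15))
  protocol <- spin_protocol(plateau_rcf = runif(1, 100, 800),
                            plateau_duration = 60,
                            reference_radius = runif(1, 30, 60))
  list(cell = cell, section = section, protocol = protocol)
}

# First-passage time of a boundary radius from a simulated trajectory.
trajectory_exit_time <- function(tr, r_exit) {
  hit <- which(abs(tr$crossings$boundary_mm - r_exit) < 1e-9)
  if (!length(hit)) return(NA_real_)
  tr$crossings$time_s[hit[1]]
}
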