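test_that("section transit time follows the Stokes closed form", {
  rbc <- cell_species("RBC", 1.098, 2.63)
  s <- medium_section("C", 1.077, 1.5, r_proximal = 30, r_distal = 37)
  omega <- speed_convert(500, 0.0335, "to_rpm") / 60  # rev/s at midpoint
  t <- section_transit_time(rbc, s, omega)
  # direct evaluation of 9*eta*ln(rd/rp) / (8*pi^2*omega^2*R^2*drho)
  expect_equal(t, 9 * 1.5e-3 * log(37 / 30) /
                 (8 * pi^2 * omega^2 * (2.63e-6)^2 * 21),
               tolerance = 1e-12)
  # equal densities: no buoyant force, non-traversable marker
  s_eq <- medium_section("C", 1.098, 1.5, 30, 37)
  expect_identical(section_transit_time(rbc, s_eq, omega), Inf)
  # denser medium likewise
  s_dense <- medium_section("C", 1.12, 1.5, 30, 37)
  expect_identical(section_transit_time(rbc, s_dense, omega), Inf)
  # halving the radius quadruples the time
  rbc_half <- cell_species("RBC", 1.098, 2.63 / 2)
  expect_equal(section_transit_time(rbc_half, s, omega), 4 * t)
  # transit undefined at the rotation axis
  s0 <- medium_section("C", 1.077, 1.5, 0, 37)
  expect_error(section_transit_time(rbc, s0, omega), "axis")
})

test_that("ramp correction reproduces the protocol arithmetic", {
  p <- spin_protocol(plateau_rcf = 500, accel_rate = 500, decel_rate = 322,
                     plateau_duration = 240)
  expect_equal(p$t_a, 60)
  expect_equal(p$t_d, 500 / 322 * 60, tolerance = 1e-12)
  expect_equal(ramp_correction(p), 2 * (p$t_a + p$t_d) / 3, tolerance = 1e-12)
  expect_equal(ramp_correction(p), 102.11, tolerance = 1e-4)
  # linearity in t_a + t_d
  p2 <- spin_protocol(plateau_rcf = 500, accel_rate = 250, decel_rate = 161,
                      plateau_duration = 240)
  expect_equal(ramp_correction(p2), 2 * ramp_correction(p))
})

test_that("migration schedules separate trapped from traversing species", {
  lane <- reference_lane()  # every section Histopaque-1077
  protocol <- spin_protocol()
  panel <- reference_cell_panel()

  lym <- migration_schedule(panel$Lymphocyte, lane, protocol)
  expect_true(lym$trapped_at_interface)
  expect_equal(nrow(lym$boundary_arrivals), 0)
  expect_identical(lym$terminal_section, "F")

  mono <- migration_schedule(panel$Monocyte, lane, protocol)
  expect_true(mono$trapped_at_interface)
  expect_equal(nrow(mono$boundary_arrivals), 0)

  neu <- migration_schedule(panel$Neutrophil, lane, protocol)
  expect_false(neu$trapped_at_interface)
  expect_equal(nrow(neu$boundary_arrivals), 6)
  expect_true(all(diff(neu$boundary_arrivals$cumulative_time_s) > 0))
  expect_identical(neu$terminal_section, "A")
  expect_equal(neu$total_time_s,
               neu$boundary_arrivals$cumulative_time_s[6] +
                 ramp_correction(protocol))
})

test_that("agglutination accelerates settling by the square of the factor", {
  lane <- reference_lane(sample_fluid = fluid_sample())
  protocol <- spin_protocol()
  rbc1 <- cell_species("RBC", 1.098, 2.63, agglutination_factor = 1)
  rbc3 <- cell_species("RBC", 1.098, 2.63, agglutination_factor = 3)
  m1 <- migration_schedule(rbc1, lane, protocol)
  m3 <- migration_schedule(rbc3, lane, protocol)
  t1 <- m1$boundary_arrivals$cumulative_time_s
  t3 <- m3$boundary_arrivals$cumulative_time_s
  expect_equal(t3, t1 / 9, tolerance = 1e-12)
})

test_that("splitting a section leaves the cumulative traversal unchanged", {
  protocol <- spin_protocol()
  cell <- cell_species("probe", 1.095, 6)
  whole <- lane_design(list(medium_section("X", 1.06, 2, 20, 40)), list(), 60)
  split <- lane_design(list(medium_section("X1", 1.06, 2, 20, 28.5),
                            medium_section("X2", 1.06, 2, 28.5, 40)),
                       list(valve_geometry(0.67, 7, 28.5)), 60)
  mw <- migration_schedule(cell, whole, protocol)
  ms <- migration_schedule(cell, split, protocol)
  expect_equal(ms$boundary_arrivals$cumulative_time_s[2],
               mw$boundary_arrivals$cumulative_time_s[1], tolerance = 1e-12)
  expect_equal(ms$total_time_s, mw$total_time_s, tolerance = 1e-12)
})

test_that("traversal time decreases in speed, radius and density contrast", {
  s <- medium_section("X", 1.05, 1.5, 20, 30)
  t_of <- function(density = 1.09, radius = 5, omega = 40)
    section_transit_time(cell_species("p", density, radius), s, omega)
  expect_true(all(diff(vapply(c(20, 40, 80), function(w) t_of(omega = w),
                              numeric(1))) < 0))
  expect_true(all(diff(vapply(c(3, 5, 8), function(r) t_of(radius = r),
                              numeric(1))) < 0))
  expect_true(all(diff(vapply(c(1.07, 1.09, 1.12), function(d)
    t_of(density = d), numeric(1))) < 0))
})

test_that("trapping occurs iff some medium is at least as dense as the cell", {
  protocol <- spin_protocol(plateau_duration = 1e6)
  set.seed(11)
  for (i in 1:25) {
    dens <- runif(4, 1.02, 1.12)
    rp <- seq(20, 50, by = 10)
    secs <- lapply(1:4, function(j)
      medium_section(LETTERS[j], dens[j], 1.5, rp[j], rp[j] + 10))
    lane <- lane_design(secs, lapply(rp[-1], function(r)
      valve_geometry(0.67, 7, r)), 60)
    cell <- cell_species("probe", runif(1, 1.03, 1.11), 5)
    res <- migration_schedule(cell, lane, protocol)
    expect_identical(res$trapped_at_interface, any(dens >= cell$density))
  }
})

test_that("partition prediction assigns every species exactly once", {
  lane <- reference_lane(sample_fluid = fluid_sample())
  protocol <- spin_protocol()
  panel <- reference_cell_panel(rbc_agglutination = 3)
  parts <- predict_partitions(panel, lane, protocol)
  expect_identical(sort(parts$species),
                   sort(unname(vapply(panel, `[[`, character(1), "name"))))
  expect_false(any(duplicated(parts$species)))
  sections <- vapply(lane$sections, `[[`, character(1), "label")
  expect_true(all(parts$section %in% sections))
})

test_that("mononuclear cells stay proximal; fast heavy particles reach A", {
  protocol <- spin_protocol()
  # all-1077 lane: lymphocytes and monocytes never leave the sample section
  lane_1077 <- reference_lane()
  parts <- predict_partitions(reference_cell_panel(), lane_1077, protocol)
  expect_identical(parts$section[parts$species == "Lymphocyte"], "F")
  expect_identical(parts$section[parts$species == "Monocyte"], "F")
  expect_true(all(parts$trapped[parts$species %in% c("Lymphocyte", "Monocyte")]))
  # a species denser than every medium with a huge radius -> distal-most
  heavy <- list(cell_species("pellet", 1.3, 50))
  lane <- reference_lane(sample_fluid = fluid_sample())
  expect_identical(predict_partitions(heavy, lane, protocol)$section, "A")
})
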