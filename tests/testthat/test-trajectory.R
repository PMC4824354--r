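test_that("constant-speed integration matches the closed form", {
  rbc <- cell_species("RBC", 1.098, 2.63)
  lane <- single_section_lane(1.077, 1.5, 30, 37)
  protocol <- spin_protocol(plateau_rcf = 500, reference_radius = 33.5,
                            plateau_duration = 120)
  omega <- protocol$plateau_rpm / 60
  t_closed <- section_transit_time(rbc, lane$sections[[1]], omega)
  tr <- simulate_trajectory(rbc, lane, protocol, ramp = "none",
                            dt = t_closed / 4000, t_end = 1.3 * t_closed)
  t_num <- trajectory_exit_time(tr, 37)
  expect_lt(abs(t_num - t_closed) / t_closed, 1e-3)
})

test_that("halving the step barely moves the crossing time", {
  cell <- cell_species("probe", 1.09, 6)
  lane <- single_section_lane(1.05, 2, 25, 40)
  protocol <- spin_protocol(plateau_rcf = 300, plateau_duration = 600)
  t1 <- trajectory_exit_time(
    simulate_trajectory(cell, lane, protocol, "none", dt = 0.1,
                        t_end = 400), 40)
  t2 <- trajectory_exit_time(
    simulate_trajectory(cell, lane, protocol, "none", dt = 0.05,
                        t_end = 400), 40)
  expect_false(is.na(t1))
  expect_lt(abs(t1 - t2) / t2, 1e-4)
})

test_that("buoyant or unspun cells do not move", {
  lane <- single_section_lane(1.10, 1.5, 25, 40)
  light <- cell_species("light", 1.05, 5)  # less dense than the medium
  protocol <- spin_protocol(plateau_duration = 60)
  tr <- simulate_trajectory(light, lane, protocol, ramp = "none", dt = 0.5)
  expect_true(all(tr$path$radius_mm == 25))
  expect_equal(nrow(tr$crossings), 0)
  # zero speed throughout the window before the ramp starts moving:
  # a protocol evaluated past its end has omega = 0
  heavy <- cell_species("heavy", 1.2, 5)
  p_short <- spin_protocol(plateau_rcf = 100, accel_rate = 6000,
                           decel_rate = 6000, plateau_duration = 1e-6)
  tr2 <- simulate_trajectory(heavy, lane, p_short, ramp = "rpm", dt = 0.05,
                             t_end = 100)
  after <- tr2$path$radius_mm[tr2$path$time_s > 5]
  expect_equal(max(after) - min(after), 0, tolerance = 1e-9)
})

test_that("positions are monotone and confined to the lane", {
  cell <- cell_species("probe", 1.12, 8)
  lane <- single_section_lane(1.02, 1.2, 20, 35)
  protocol <- spin_protocol(plateau_rcf = 500, plateau_duration = 600)
  tr <- simulate_trajectory(cell, lane, protocol, ramp = "rcf", dt = 0.1)
  expect_true(all(diff(tr$path$radius_mm) >= 0))
  expect_true(all(tr$path$radius_mm >= 20 & tr$path$radius_mm <= 35))
})

test_that("ramp shapes deliver 1/2 (RCF-linear) and 1/3 (RPM-linear) of plateau sedimentation", {
  # weak settler so the distal wall is never reached during the window
  cell <- cell_species("probe", 1.002, 5)
  lane <- single_section_lane(1.0, 1.0, 20, 60)
  protocol <- spin_protocol(plateau_rcf = 500, accel_rate = 500,
                            plateau_duration = 60)
  ta <- protocol$t_a
  ln_disp <- function(ramp) {
    tr <- simulate_trajectory(cell, lane, protocol, ramp = ramp, dt = 0.01,
                              t_end = ta)
    log(tr$path$radius_mm[nrow(tr$path)] / 20)
  }
  plateau <- ln_disp("none")
  expect_equal(ln_disp("rcf") / plateau, 1 / 2, tolerance = 1e-4)
  expect_equal(ln_disp("rpm") / plateau, 1 / 3, tolerance = 1e-4)
})

test_that("boundary crossings are detected in radial order", {
  cell <- cell_species("probe", 1.11, 7)
  lane <- reference_lane(sample_fluid = fluid_sample())
  protocol <- spin_protocol(plateau_duration = 2000)
  tr <- simulate_trajectory(cell, lane, protocol, ramp = "none", dt = 0.2)
  expect_gt(nrow(tr$crossings), 1)
  expect_true(all(diff(tr$crossings$time_s) > 0))
  expect_true(all(diff(tr$crossings$boundary_mm) > 0))
  expect_identical(tr$crossings$section_entered[1], "E")
})
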