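test_that("the controller implements the stagnation, scale-down and clamp rules", {
  proto <- pull_protocol()
  st <- function(a, stag = 0, step = 1, v = NA) {
    list(current_acceleration = a, steps_since_max_increase = stag,
         step_index = step, max_dis_speed = v)
  }
  # stagnant for the full window: +500
  expect_equal(update_acceleration(st(2000, stag = 400), proto), 2500)
  # one step short of the window: unchanged
  expect_equal(update_acceleration(st(2000, stag = 399), proto), 2000)
  # at the cap exactly the scale factor is 1
  expect_equal(update_acceleration(st(3000, step = 20, v = 4000), proto), 3000)
  # v twice the cap: a * (1 - (1 - 1/2)^2) = 3/4 a
  expect_equal(update_acceleration(st(4000, step = 20, v = 8000), proto), 3000)
  # scale-down never goes below the floor
  expect_equal(update_acceleration(st(2100, step = 20, v = 40000), proto), 2000)
  # speed checks only fire on multiples of the check interval
  expect_equal(update_acceleration(st(4000, step = 19, v = 8000), proto), 4000)
})

test_that("force conversion follows F = m a c", {
  expect_equal(force_from_acceleration(1, 1), 0.00166)
  expect_equal(force_from_acceleration(100, 0), 0)
  expect_equal(force_from_acceleration(624.24, 2000), 624.24 * 2000 * 0.00166)
  expect_error(force_from_acceleration(-1, 2000), class = "msc_value_error")
})

test_that("protocol invariants are validated", {
  expect_error(pull_protocol(a_increment = 3000), class = "msc_value_error")
  expect_error(pull_protocol(stop_displacement = 0), class = "msc_value_error")
  expect_silent(pull_protocol())
})

test_that("system building assigns parameters and rejects clashes", {
  free <- free_particle_system()
  expect_s3_class(free, "pull_system")
  expect_null(free$receptor)

  sys <- gen_pull_system(30, n_ligand = 5, sticky_residues = 3L, seed = 4)
  expect_identical(nrow(sys$receptor), 30L)
  expect_true(sys$receptor$apolar[3])
  expect_false(any(sys$receptor$apolar[-3]))
  expect_identical(nrow(sys$bonds), 4L)

  rec <- data.frame(residue_id = 1, x = 0.5, y = 0, z = 0, apolar = TRUE)
  lig <- data.frame(x = 0, y = 0, z = 0, mass = 100, apolar = TRUE)
  expect_error(build_system(rec, lig), class = "msc_clash_error")
})

test_that("a free particle obeys the constant-acceleration closed forms", {
  proto <- pull_protocol(equilibration_time = 0)
  res <- run_pull(free_particle_system(), proto, init_temperature = 0)
  # time to 15 A at 20 A/ps^2: sqrt(2 d / a)
  expect_equal(res$time_ps, sqrt(2 * 15 / 20), tolerance = 0.01)
  # work = F d with F = m a c
  expect_equal(res$total_work, 624.24 * 2000 * 0.00166 * 15, tolerance = 0.01)
  # acceleration never left the floor (no stagnation, speed below cap)
  expect_true(all(res$acceleration_series == 2000))
  expect_equal(res$peak_force, 624.24 * 2000 * 0.00166, tolerance = 1e-9)
  expect_gte(res$displacement_series[res$n_steps], 15)
  # displacement is monotone for the free particle
  expect_true(all(diff(res$displacement_series) > 0))
})

test_that("pull runs are bit-reproducible for a fixed seed", {
  sys <- gen_pull_system(20, sticky_residues = 5L, seed = 6)
  a <- run_pull(sys, seed = 42)
  b <- run_pull(sys, seed = 42)
  expect_identical(a$displacement_series, b$displacement_series)
  expect_identical(a$acceleration_series, b$acceleration_series)
  expect_identical(a$total_work, b$total_work)
  c <- run_pull(sys, seed = 43)
  expect_false(identical(a$displacement_series, c$displacement_series))
})

test_that("a ligand bound in a deep well forces controller escalation", {
  sys <- gen_pull_system(25, sticky_residues = 7L, seed = 2)
  res <- run_pull(sys, seed = 2)
  floor_force <- force_from_acceleration(624.24, 2000)
  expect_gt(res$peak_force, floor_force)
  expect_gt(max(res$acceleration_series), 2000)
  expect_true(all(res$acceleration_series >= 2000))
  expect_gte(res$displacement_series[res$n_steps], 15)
})

test_that("prolonged contacts recover exactly the planted sticky residue", {
  sys <- gen_pull_system(25, sticky_residues = 7L, seed = 2)
  res <- run_pull(sys, seed = 2)
  expect_identical(prolonged_contacts(res), 7L)

  none <- run_pull(gen_pull_system(25, seed = 3), seed = 3)
  expect_identical(prolonged_contacts(none), integer(0))
})

test_that("persistence thresholding separates transient from prolonged contact", {
  fake <- structure(
    list(contact_counts = stats::setNames(c(100L, 10L), c("5", "9")),
         n_steps = 100L),
    class = "pull_result")
  expect_identical(prolonged_contacts(fake, 0.5), 5L)
  expect_identical(prolonged_contacts(fake, 0.05), c(5L, 9L))
  empty <- structure(list(contact_counts = integer(0), n_steps = 10L),
                     class = "pull_result")
  expect_identical(prolonged_contacts(empty), integer(0))
})

test_that("the non-termination guard trips when displacement is unreachable", {
  proto <- pull_protocol(equilibration_time = 0, max_steps = 50L)
  expect_error(run_pull(free_particle_system(), proto, init_temperature = 0),
               class = "msc_nontermination_error")
})
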