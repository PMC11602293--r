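test_that("superposition is exact on rigid copies and matches the search oracle", {
  set.seed(21)
  ref <- matrix(rnorm(15), 5, 3)

  id <- kabsch_superpose(ref, ref)
  expect_equal(id$rmsd, 0, tolerance = 1e-12)
  expect_equal(id$rotation, diag(3), tolerance = 1e-9)

  th <- pi / 2
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
               3, byrow = TRUE)
  rotated <- ref %*% t(Rz) + matrix(c(5, -2, 1), 5, 3, byrow = TRUE)
  fit <- kabsch_superpose(rotated, ref)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-10)

  # one displaced atom: least-squares minimum must match a numerical
  # rotation-search oracle
  mob <- ref[1:4, ]
  mob[2, ] <- mob[2, ] + c(1, 0, 0)
  expect_equal(kabsch_superpose(mob, ref[1:4, ])$rmsd,
               oracle_superpose_rmsd(mob, ref[1:4, ]), tolerance = 1e-6)
})

test_that("superposition agrees with an independent library fit", {
  set.seed(22)
  a <- matrix(rnorm(24), 8, 3)
  b <- a + matrix(rnorm(24, sd = 0.3), 8, 3)
  mine <- kabsch_superpose(b, a)$rmsd
  other <- suppressWarnings(bio3d::fit.xyz(as.vector(t(a)), as.vector(t(b))))
  other_rmsd <- sqrt(mean(rowSums((matrix(other, ncol = 3, byrow = TRUE) - a)^2)))
  expect_equal(mine, other_rmsd, tolerance = 1e-8)
})

test_that("degenerate atom sets are rejected", {
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line),
               class = "msc_degenerate_superposition_error")
  two <- matrix(rnorm(6), 2, 3)
  expect_error(kabsch_superpose(two, two),
               class = "msc_degenerate_superposition_error")
})

test_that("RMSF matches hand calculations and the jitter closed form", {
  # identical frames -> zero fluctuation
  coords <- array(rep(c(1, 2, 3), each = 4), c(4, 1, 3))
  tr <- msc_trajectory(coords)
  expect_equal(compute_rmsf(tr, 0, superpose = FALSE)$rmsf, 0)

  # single atom alternating (0,0,0)/(2,0,0): mean (1,0,0), deviation 1
  alt <- array(0, c(4, 1, 3))
  alt[c(2, 4), 1, 1] <- 2
  expect_equal(compute_rmsf(msc_trajectory(alt), 0, superpose = FALSE)$rmsf, 1)

  # isotropic jitter sd sigma -> E[RMSF] = sigma * sqrt(3)
  spec <- flexibility_spec(sigma = rep(0.5, 12), n_frames = 2000)
  prof <- compute_rmsf(gen_trajectory(spec, "low", seed = 7), 0.5,
                       superpose = FALSE)
  expect_true(all(abs(prof$rmsf / (0.5 * sqrt(3)) - 1) < 0.05))
})

test_that("equilibration handling discards the leading fraction", {
  coords <- array(0, c(10, 2, 3))
  coords[1:5, , 1] <- 100          # wild first half, quiet second half
  tr <- msc_trajectory(coords)
  expect_equal(compute_rmsf(tr, 0.5, superpose = FALSE)$rmsf, c(0, 0))
  expect_error(compute_rmsf(msc_trajectory(coords[1:2, , , drop = FALSE]), 0.5),
               class = "msc_insufficient_frames_error")
})

test_that("RMSF is invariant under per-frame rigid motions when superposing", {
  spec <- flexibility_spec(sigma = runif(8, 0.2, 0.6), n_frames = 60)
  tr <- gen_trajectory(spec, "low", seed = 3)
  base <- compute_rmsf(tr, 0, superpose = TRUE)
  moved <- tr
  set.seed(31)
  for (f in seq_len(dim(tr$coords)[1])) {
    ang <- runif(3, 0, 2 * pi)
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    R <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE) %*%
      matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    moved$coords[f, , ] <- tr$coords[f, , ] %*% t(R) +
      matrix(runif(3, -5, 5), dim(tr$coords)[2], 3, byrow = TRUE)
  }
  expect_equal(compute_rmsf(moved, 0, superpose = TRUE)$rmsf, base$rmsf,
               tolerance = 1e-8)
})

test_that("delta RMSF reproduces tabulated differences and is antisymmetric", {
  mk <- function(ids, vals, temp) {
    structure(list(residue_ids = ids, rmsf = vals, temperature = temp,
                   equilibration_fraction = 0.5, n_frames = 2),
              class = "rmsf_profile")
  }
  hi <- mk(c(67L, 61L), c(1.368, 1.215), 328)
  lo <- mk(c(67L, 61L), c(0.526, 1.325), 298)
  d <- delta_rmsf(hi, lo)
  expect_equal(d$delta[d$residue == 67], 0.842, tolerance = 1e-9)
  expect_equal(d$delta[d$residue == 61], -0.110, tolerance = 1e-9)
  expect_equal(delta_rmsf(lo, hi)$delta, -d$delta)
  expect_equal(delta_rmsf(hi, hi)$delta, c(0, 0))
  expect_error(delta_rmsf(hi, mk(c(67L, 62L), c(1, 1), 298)),
               class = "msc_alignment_error")
})

test_that("radius of gyration matches hand calculations", {
  expect_equal(radius_of_gyration(matrix(c(4, 5, 6), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1)
  sq <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0), c(2, 2, 0))
  expect_equal(radius_of_gyration(sq), sqrt(2))
  # mass weighting pulls Rg toward the heavy atom
  expect_lt(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)), c(10, 1)),
            1)
})

test_that("hydrogen-bond counting follows the geometric criterion", {
  D <- matrix(c(0, 0, 0), 1, 3)
  expect_identical(count_hydrogen_bonds(D, matrix(numeric(0), 0, 3)), 0L)
  expect_identical(count_hydrogen_bonds(D, matrix(c(3, 0, 0), 1, 3)), 1L)
  expect_identical(count_hydrogen_bonds(D, matrix(c(3.6, 0, 0), 1, 3)), 0L)
  # with an explicit hydrogen: 170 degrees passes, 90 degrees fails
  H <- matrix(c(1, 0, 0), 1, 3)
  A_line <- matrix(c(3, 0.35, 0), 1, 3)      # nearly linear D-H...A
  A_side <- matrix(c(1, 2, 0), 1, 3)         # right angle at H
  expect_identical(count_hydrogen_bonds(D, A_line, H), 1L)
  expect_identical(count_hydrogen_bonds(D, A_side, H), 0L)
})

test_that("SASA matches the isolated-sphere closed form and converges", {
  single <- shrake_rupley_sasa(matrix(0, 1, 3), radii = 1.9)
  expect_equal(as.numeric(single), 4 * pi * 3.3^2, tolerance = 0.02)

  # atom caged by large neighbours is essentially buried
  cage <- rbind(c(0, 0, 0),
                c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0),
                c(0, -3, 0), c(0, 0, 3), c(0, 0, -3))
  caged <- shrake_rupley_sasa(cage, radii = c(1.2, rep(3.5, 6)))
  expect_lt(attr(caged, "per_atom")[1], 1)

  set.seed(41)
  fixture <- matrix(rnorm(30, sd = 2.5), 10, 3)
  s1 <- as.numeric(shrake_rupley_sasa(fixture, radii = 1.7,
                                      n_sphere_points = 960))
  s2 <- as.numeric(shrake_rupley_sasa(fixture, radii = 1.7,
                                      n_sphere_points = 1920))
  expect_lt(abs(s1 - s2) / s2, 0.01)
})

test_that("RMSD series is zero against itself and rigid-motion invariant", {
  spec <- flexibility_spec(sigma = rep(0.3, 6), n_frames = 10)
  tr <- gen_trajectory(spec, "low", seed = 2)
  rs <- rmsd_series(tr)
  expect_equal(rs[1], 0, tolerance = 1e-10)
  expect_true(all(rs >= 0))
})
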