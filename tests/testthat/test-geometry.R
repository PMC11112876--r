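test_that("center of mass is the mass-weighted mean position", {
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(0, 0, 2))), c(0, 0, 1))
  expect_equal(center_of_mass(rbind(c(0, 0, 0), c(1, 0, 0)),
                              masses = c(12, 16))[1], 16 / 28)
  p <- c(1.5, -2, 7)
  expect_equal(center_of_mass(rbind(p)), p)
  expect_error(center_of_mass(matrix(numeric(0), 0, 3)), "empty")
})

test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(1)
  ref <- matrix(rnorm(30), 10, 3)
  fit0 <- kabsch_superpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  R <- rotation_matrix(c(0, 0, 1), 90)
  mobile <- sweep(ref %*% t(R), 2L, c(5, 5, 5), `+`)
  fit <- kabsch_superpose(mobile, ref)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_error(kabsch_superpose(ref[1:4, ], ref), "same number")
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "3 points")
})

test_that("mirror images are fitted with a proper rotation, matching the
           rotation-scan oracle", {
  set.seed(7)
  ref <- matrix(rnorm(12, sd = 2), 4, 3)       # scalene 4-point set
  mirror <- ref %*% diag(c(-1, 1, 1))
  fit <- kabsch_superpose(mirror, ref)
  expect_gt(fit$rmsd, 0.1)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  oracle <- grid_min_rmsd(mirror, ref)
  expect_equal(fit$rmsd, oracle, tolerance = 1e-4)
  expect_lte(fit$rmsd, oracle + 1e-6)
})

test_that("RMSD series is zero for static and rigidly rotating
           trajectories and matches an independent route otherwise", {
  set.seed(2)
  base <- matrix(rnorm(36, sd = 3), 12, 3)
  atoms <- data.frame(serial = 1:12, atom_name = "CA",
                      residue_name = "ALA", chain_id = "A",
                      residue_number = 1:12, element = "C", mass = 12.011,
                      is_water = FALSE)
  static <- trajectory(atoms, t(sapply(1:4, function(k) as.vector(t(base)))))
  expect_equal(rmsd_series(static, 1:12), rep(0, 4), tolerance = 1e-12)

  rot <- t(sapply(0:3, function(k) {
    as.vector(t(base %*% t(rotation_matrix(c(1, 2, 3), k * 30))))
  }))
  rot_traj <- trajectory(atoms, rot)
  expect_lt(max(rmsd_series(rot_traj, 1:12)), 1e-9)

  # jittered 2-frame case against bio3d's independent superposition route
  jit <- rbind(as.vector(t(base)),
               as.vector(t(base + matrix(rnorm(36, sd = 0.4), 12, 3))))
  jit_traj <- trajectory(atoms, jit)
  ours <- rmsd_series(jit_traj, 1:12)[2]
  fitted <- bio3d::fit.xyz(jit[1, ], jit, fixed.inds = 1:36,
                           mobile.inds = 1:36)
  dx <- matrix(fitted[2, ] - fitted[1, ], ncol = 3, byrow = TRUE)
  theirs <- sqrt(mean(rowSums(dx^2)))
  expect_equal(ours, theirs, tolerance = 1e-6)
  expect_error(rmsd_series(jit_traj, 1:12, reference_frame = 9), "range")
})

test_that("RMSF of isotropic per-coordinate jitter approaches sigma*sqrt(3)", {
  set.seed(3)
  sigma <- 0.25
  n_at <- 40L; n_fr <- 400L
  base <- cbind(seq(0, 39) * 1.5, 2.3 * cos(seq(0, 39)),
                2.3 * sin(seq(0, 39)))
  atoms <- data.frame(serial = 1:n_at, atom_name = "CA",
                      residue_name = "ALA", chain_id = "A",
                      residue_number = 1:n_at, element = "C", mass = 12.011,
                      is_water = FALSE)
  xyz <- t(sapply(seq_len(n_fr), function(k) {
    as.vector(t(base + matrix(rnorm(3 * n_at, sd = sigma), n_at, 3)))
  }))
  tr <- trajectory(atoms, xyz)
  r <- rmsf_per_residue(tr, 1:n_at)
  # alignment to the mean removes ~6 of the 3M fluctuation DOF
  expect_equal(mean(r), sigma * sqrt(3) * sqrt(1 - 6 / (3 * n_at)),
               tolerance = 0.05)
  # static input gives zeros, single frame errors
  static <- trajectory(atoms, xyz[c(1, 1), ])
  expect_equal(unname(rmsf_per_residue(static, 1:n_at)), rep(0, n_at),
               tolerance = 1e-12)
  expect_error(rmsf_per_residue(trajectory(atoms, xyz[1, , drop = FALSE]),
                                1:n_at), "2 frames")
})

test_that("jitter confined to one residue stays confined after alignment", {
  set.seed(4)
  n_at <- 30L
  base <- matrix(rnorm(3 * n_at, sd = 6), n_at, 3)
  atoms <- data.frame(serial = 1:n_at, atom_name = "CA",
                      residue_name = "ALA", chain_id = "A",
                      residue_number = 1:n_at, element = "C", mass = 12.011,
                      is_water = FALSE)
  xyz <- t(sapply(1:200, function(k) {
    b <- base
    b[5, ] <- b[5, ] + rnorm(3, sd = 0.5)
    as.vector(t(b))
  }))
  r <- rmsf_per_residue(trajectory(atoms, xyz), 1:n_at)
  expect_gt(r[5], 5 * max(r[-5]))
})

test_that("axis fitting is total least squares with N-to-C orientation", {
  col <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  f <- fit_axis(col)
  expect_equal(f$direction, c(0, 0, 1))
  expect_equal(f$residual_rms, 0)
  # reversing the point order flips the sign
  expect_equal(fit_axis(col[3:1, ])$direction, c(0, 0, -1))

  i <- 0:21
  helix <- cbind(2.3 * cos(i * 100 * pi / 180),
                 2.3 * sin(i * 100 * pi / 180), 1.5 * i)
  # a finite helix's TLS axis wobbles slightly off the geometric axis
  # (unbalanced sampled phases); 22 residues at 100 deg/res sit ~1.4 deg off
  fh <- fit_axis(helix)
  wobble <- axis_angle(fh, list(direction = c(0, 0, 1)))
  expect_lt(wobble, 2)
  # rotation equivariance is exact: the wobble is carried along unchanged
  R <- rotation_matrix(c(1, 0, 0), 30)
  fr <- fit_axis(helix %*% t(R))
  expect_equal(axis_angle(fr, list(direction = as.numeric(R %*% c(0, 0, 1)))),
               wobble, tolerance = 1e-6)
  expect_error(fit_axis(col[1:2, ]), "3 points")
  expect_error(fit_axis(matrix(1, 4, 3)), "coincident")
})

test_that("axis angles are oriented arc-cosines in degrees", {
  za <- list(direction = c(0, 0, 1))
  expect_equal(axis_angle(za, za), 0)
  expect_equal(axis_angle(za, list(direction = c(0, 1, 0))), 90)
  t10 <- list(direction = c(0, sin(10 * pi / 180), cos(10 * pi / 180)))
  expect_equal(axis_angle(za, t10), 10, tolerance = 1e-9)
  expect_equal(axis_angle(za, list(direction = c(0, 0, -1))), 180)
})

test_that("pair distances use selection centers of mass", {
  atoms <- data.frame(serial = 1:2, atom_name = "CA",
                      residue_name = "ALA", chain_id = "A",
                      residue_number = 1:2, element = "C", mass = 12.011,
                      is_water = FALSE)
  xyz <- rbind(as.vector(t(rbind(c(0, 0, 0), c(3, 4, 0)))),
               as.vector(t(rbind(c(1, 1, 1), c(4, 5, 1)))))
  tr <- trajectory(atoms, xyz)
  expect_equal(pair_distance_series(tr, 1L, 2L, mode = "single"), c(5, 5))
  expect_equal(pair_distance_series(tr, 1L, 1L), c(0, 0))
  expect_error(pair_distance_series(tr, integer(0), 2L), "empty")
})

test_that("geometry is invariant (or equivariant) under global rigid motion", {
  b <- build_hexamer(tiny_params(n_frames = 3L, jitter_sigma = 0.1))
  tr <- b$trajectory
  ca <- select_atoms(tr, chain = "A", atom_names = "CA")
  set.seed(9)
  for (k in 1:3) {
    R <- random_rotation(); tvec <- rnorm(3, sd = 20)
    tr2 <- rigid_motion_traj(tr, R, tvec)
    expect_equal(rmsd_series(tr2, ca), rmsd_series(tr, ca),
                 tolerance = 1e-8)
    expect_equal(pair_distance_series(tr2, ca[1], ca[22]),
                 pair_distance_series(tr, ca[1], ca[22]), tolerance = 1e-8)
    f1 <- fit_axis(frame_coords(tr, 1, ca[1:22]))
    f2 <- fit_axis(frame_coords(tr2, 1, ca[1:22]))
    expect_equal(as.numeric(R %*% f1$direction), f2$direction,
                 tolerance = 1e-8)
  }
})

test_that("superposed RMSD never exceeds unsuperposed RMSD", {
  set.seed(5)
  for (k in 1:5) {
    a <- matrix(rnorm(30), 10, 3)
    b <- a + matrix(rnorm(30, sd = 0.5), 10, 3)
    naive <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(kabsch_superpose(a, b)$rmsd, naive + 1e-12)
  }
})
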