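test_that("channel definitions are validated", {
  segs <- list(TM1 = c(15, 36), TM2 = c(75, 96), TM3 = c(144, 165),
               TM4 = c(210, 231))
  ch <- channel_definition(tm_segments = segs)
  expect_s3_class(ch, "channel_definition")
  expect_equal(ch$bridge_cutoff, 4.0)
  expect_equal(ch$water_cutoff, 6.0)
  expect_length(ch$pocket_residues, 30L)
  expect_error(channel_definition(protomer_chains = LETTERS[1:4]),
               "6 protomer chains")
  expect_error(channel_definition(tm_segments = segs, bridge_cutoff = 0),
               "positive")
  bad <- segs; bad$TM2 <- c(20, 40)              # overlaps TM1
  expect_error(channel_definition(tm_segments = bad), "disjoint")
  bad2 <- segs; bad2$TM1 <- c(26, 47)            # residue 25 outside
  expect_error(channel_definition(tm_segments = bad2), "outside")
})

test_that("channel config files round-trip through JSON", {
  b <- build_hexamer(tiny_params(n_frames = 1L))
  f <- withr::local_tempfile(fileext = ".json")
  write_channel_config(b$channel, f)
  ch2 <- read_channel_config(f)
  expect_equal(ch2$tm_segments, lapply(b$channel$tm_segments, as.numeric))
  expect_equal(ch2$pocket_residues, as.numeric(b$channel$pocket_residues))
  expect_equal(ch2$moiety_map, b$channel$moiety_map)
})

test_that("salt-bridge occupancy follows the 4 A criterion frame by frame", {
  ch <- channel_definition()
  always <- toy_bridge_traj(rep(3.5, 6))
  br <- saltbridge_series(always, ch, c("A", 1), c("A", 2))
  expect_equal(br$series, rep(3.5, 6))
  expect_equal(br$occupancy, 1)
  expect_true(br$bridged)

  alternating <- toy_bridge_traj(rep(c(3.5, 4.5), 3))
  br2 <- saltbridge_series(alternating, ch, c("A", 1), c("A", 2))
  expect_equal(br2$occupancy, 0.5)
  expect_true(br2$bridged)          # boundary rule: occupancy >= 0.5

  never <- toy_bridge_traj(rep(6.0, 4))
  br3 <- saltbridge_series(never, ch, c("A", 1), c("A", 2))
  expect_equal(br3$occupancy, 0)
  expect_false(br3$bridged)
  expect_equal(unname(br3$summary["mean"]), 6.0)
})

test_that("bridge errors name the offending residue and atoms", {
  b <- build_hexamer(tiny_params(n_frames = 1L))
  ch <- b$channel
  # residue 20 is ALA: no terminal-moiety definition
  expect_error(saltbridge_series(b$trajectory, ch, c("A", 20), c("A", 162)),
               "no terminal-moiety definition")
  # drop one moiety atom of A:33 and expect it listed
  tr <- b$trajectory
  drop <- select_atoms(tr, chain = "A", residue_numbers = 33,
                       atom_names = "NH1")
  keep <- setdiff(seq_len(nrow(tr$atoms)), drop)
  keep_xyz <- as.vector(t(outer(keep, 1:3,
                                function(i, j) 3L * (i - 1L) + j)))
  tr2 <- trajectory(tr$atoms[keep, ],
                    tr$xyz[, keep_xyz, drop = FALSE])
  expect_error(saltbridge_series(tr2, ch, c("A", 33), c("A", 162)), "NH1")
})

test_that("bridged-protomer counts reflect the planted pattern", {
  b <- build_hexamer(tiny_params(n_frames = 4L))
  expect_equal(bridged_protomer_count(b$trajectory, b$channel, c(158, 223)),
               4L)
  expect_equal(bridged_protomer_count(b$trajectory, b$channel, c(33, 162)),
               6L)
  none <- default_bridge_plants()
  none$dwell <- 0
  b0 <- build_hexamer(tiny_params(n_frames = 4L, bridge_plants = none))
  expect_equal(bridged_protomer_count(b0$trajectory, b0$channel,
                                      c(158, 223)), 0L)
  expect_equal(bridged_protomer_count(b0$trajectory, b0$channel,
                                      c(33, 162)), 0L)
})

test_that("raising the bridge cutoff never decreases the bridged count", {
  b <- build_hexamer(tiny_params(n_frames = 4L, jitter_sigma = 0.1))
  counts <- vapply(c(3, 4, 5, 6.5), function(cut) {
    ch <- b$channel; ch$bridge_cutoff <- cut
    bridged_protomer_count(b$trajectory, ch, c(158, 223))
  }, integer(1))
  expect_false(is.unsorted(counts))
})

test_that("TM distances match the construction and are rigid-invariant", {
  b <- build_hexamer(tiny_params(n_frames = 2L))
  tr <- b$trajectory; ch <- b$channel; m <- b$manifest
  for (p in ch$protomer_chains) {
    expect_equal(tm_distance(tr, ch, p, "TM1-TM3")[1],
                 unname(m$rep_distances[[p]]["TM1-TM3"]), tolerance = 1e-6)
    expect_equal(tm_distance(tr, ch, p, "TM2-TM4")[1],
                 unname(m$rep_distances[[p]]["TM2-TM4"]), tolerance = 1e-6)
  }
  # close to the planted 11 A axis separation by construction
  expect_equal(tm_distance(tr, ch, "A", "TM2-TM4")[1], 11, tolerance = 0.5)
  shifted <- rigid_motion_traj(tr, diag(3), c(30, -12, 4))
  expect_equal(tm_distance(shifted, ch, "C", "TM1-TM3"),
               tm_distance(tr, ch, "C", "TM1-TM3"), tolerance = 1e-9)
  expect_error(tm_distance(tr, ch, "Z", "TM1-TM3"), "missing")
})

test_that("TM inclinations recover parallel, antiparallel and tilted
           plantings", {
  b <- build_hexamer(tiny_params(n_frames = 1L))
  tr <- b$trajectory; ch <- b$channel
  expect_lt(tm_inclination(tr, ch, "A", "TM3")[1], 1)      # parallel
  expect_gt(tm_inclination(tr, ch, "A", "TM2")[1], 179)    # antiparallel
  expect_gt(tm_inclination(tr, ch, "A", "TM4")[1], 179)

  tb <- build_hexamer(tiny_params(n_frames = 1L,
                                  tm_tilts = list(B = c(TM3 = 12))))
  expect_equal(tm_inclination(tb$trajectory, tb$channel, "B", "TM3")[1],
               12, tolerance = 1)
  expect_lt(tm_inclination(tb$trajectory, tb$channel, "A", "TM3")[1], 1)
  # channels without TM segments cannot compute axis metrics
  ch0 <- channel_definition()
  expect_error(tm_inclination(tr, ch0, "A", "TM3"), "tm_segments")
})

test_that("pocket water counting includes the 6.0 A boundary", {
  atoms <- data.frame(
    serial = 1:5,
    atom_name = c("CA", "CA", "CA", "O", "O"),
    residue_name = c("ALA", "ALA", "ALA", "HOH", "HOH"),
    chain_id = c("A", "A", "A", "W", "W"),
    residue_number = c(1L, 2L, 3L, 1L, 2L),
    element = c("C", "C", "C", "O", "O"),
    mass = c(rep(12.011, 3), rep(15.999, 2)),
    is_water = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # centroid of the three CA is the origin
  coords <- rbind(c(1, 0, 0), c(-0.5, 0.866, 0), c(-0.5, -0.866, 0),
                  c(5.9, 0, 0), c(6.1, 0, 0))
  tr <- trajectory(atoms, matrix(as.vector(t(coords)), 1))
  ch <- channel_definition(pocket_residues = 1:3)
  expect_equal(pocket_water_count(tr, ch, "A", quiet = TRUE), 1L)
  # exactly at the boundary counts (<= rule)
  coords[5, ] <- c(6.0, 0, 0)
  tr2 <- trajectory(atoms, matrix(as.vector(t(coords)), 1))
  expect_equal(pocket_water_count(tr2, ch, "A", quiet = TRUE), 2L)
  # no waters at all
  tr3 <- trajectory(atoms[1:3, ], matrix(as.vector(t(coords[1:3, ])), 1))
  expect_equal(pocket_water_count(tr3, ch, "A", quiet = TRUE), 0L)
  expect_error(pocket_water_count(tr, ch, "B", quiet = TRUE), "no pocket")
})

test_that("pocket counts equal a brute-force distance scan and are
           monotone in the cutoff", {
  b <- build_hexamer(tiny_params(n_frames = 3L, jitter_sigma = 0.15,
                                 seed = 21L))
  tr <- b$trajectory; ch <- b$channel
  for (p in c("A", "D", "F")) {
    ours <- pocket_water_count(tr, ch, p, quiet = TRUE)
    for (f in 1:3) expect_equal(ours[f], brute_pocket_count(tr, ch, p, f))
  }
  cuts <- c(2, 4, 6, 8, 12)
  counts <- vapply(cuts, function(cut) {
    ch2 <- ch; ch2$water_cutoff <- cut
    pocket_water_count(tr, ch2, "B", quiet = TRUE)[1]
  }, integer(1))
  expect_false(is.unsorted(counts))
})

test_that("pocket water series pools protomers and replicas", {
  b <- build_hexamer(tiny_params(n_frames = 3L))
  s1 <- pocket_water_series(b$trajectory, b$channel, quiet = TRUE)
  expect_equal(nrow(s1$table), 3L * 6L)
  expect_equal(length(s1$pooled), 3L * 6L)
  # zero jitter: planted count everywhere
  expect_true(all(s1$pooled == b$manifest$pocket_counts[1]))
  # two replicas with planted counts 6 and 12
  b2 <- build_hexamer(tiny_params(n_frames = 3L, n_pocket_waters = 12L,
                                  seed = 12L))
  s2 <- pocket_water_series(list(b$trajectory, b2$trajectory), b$channel,
                            quiet = TRUE)
  expect_equal(length(s2$pooled), 2L * 3L * 6L)
  expect_equal(unname(s2$per_frame_mean), rep(9, 3))
  expect_equal(unname(s2$per_frame_sd), rep(stats::sd(c(6, 12)), 3))
})

test_that("channel metrics are invariant under a global rigid motion", {
  b <- build_hexamer(tiny_params(n_frames = 2L, jitter_sigma = 0.1))
  tr <- b$trajectory; ch <- b$channel
  set.seed(33)
  tr2 <- rigid_motion_traj(tr, random_rotation(), rnorm(3, sd = 15))
  expect_equal(saltbridge_series(tr2, ch, c("B", 33), c("B", 162))$series,
               saltbridge_series(tr, ch, c("B", 33), c("B", 162))$series,
               tolerance = 1e-8)
  expect_equal(tm_inclination(tr2, ch, "E", "TM3"),
               tm_inclination(tr, ch, "E", "TM3"), tolerance = 1e-7)
  expect_identical(pocket_water_count(tr2, ch, "C", quiet = TRUE),
                   pocket_water_count(tr, ch, "C", quiet = TRUE))
})
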