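# Shared fixtures and independent oracles.

# Small synthetic hexamer for fast tests.
tiny_params <- function(...) {
  args <- list(...)
  defaults <- list(n_frames = 4L, n_pocket_waters = 6L, n_bulk_waters = 40L,
                   jitter_sigma = 0, seed = 11L)
  do.call(synthesis_params, utils::modifyList(defaults, args))
}

# Brute-force pocket water count: explicit per-water distance scan, no
# vectorisation shared with the implementation.
brute_pocket_count <- function(traj, channel, protomer, frame) {
  a <- traj$atoms
  pidx <- which(a$chain_id == protomer & a$atom_name == "CA" &
                a$residue_number %in% channel$pocket_residues)
  xyz <- frame_coords(traj, frame)
  cen <- c(0, 0, 0); mt <- 0
  for (i in pidx) {
    cen <- cen + a$mass[i] * xyz[i, ]
    mt <- mt + a$mass[i]
  }
  cen <- cen / mt
  n <- 0L
  for (i in which(a$is_water)) {
    d <- sqrt((xyz[i, 1] - cen[1])^2 + (xyz[i, 2] - cen[2])^2 +
              (xyz[i, 3] - cen[3])^2)
    if (d <= channel$water_cutoff) n <- n + 1L
  }
  n
}

# Brute-force minimal RMSD over rotations: coarse Euler-angle grid scan
# followed by Nelder-Mead refinement. Independent of the SVD route.
grid_min_rmsd <- function(mobile, reference) {
  P <- sweep(mobile, 2L, colMeans(mobile))
  Q <- sweep(reference, 2L, colMeans(reference))
  euler_rot <- function(a, b, c) {
    rotation_matrix(c(0, 0, 1), a) %*% rotation_matrix(c(0, 1, 0), b) %*%
      rotation_matrix(c(1, 0, 0), c)
  }
  rmsd_of <- function(ang) {
    R <- euler_rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((P %*% t(R) - Q)^2)))
  }
  best <- NULL; best_v <- Inf
  for (a in seq(0, 350, by = 20)) {
    for (b in seq(0, 180, by = 20)) {
      for (c in seq(0, 350, by = 20)) {
        v <- rmsd_of(c(a, b, c))
        if (v < best_v) { best_v <- v; best <- c(a, b, c) }
      }
    }
  }
  opt <- stats::optim(best, rmsd_of, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-14))
  opt$value
}

# Tie-corrected Kruskal-Wallis H by the direct rank-sum formula.
kw_formula <- function(groups) {
  x <- unlist(groups)
  N <- length(x)
  r <- rank(x)
  splits <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(splits, function(ri) sum(ri)^2 / length(ri), numeric(1))) -
    3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# Toy trajectory: two residues whose moiety atoms all sit at single
# points, so the moiety COM distance is set exactly per frame.
toy_bridge_traj <- function(distances) {
  atoms <- data.frame(
    serial = 1:7,
    atom_name = c("CZ", "NH1", "NH2", "NE", "CD", "OE1", "OE2"),
    residue_name = c(rep("ARG", 4), rep("GLU", 3)),
    chain_id = "A", residue_number = c(rep(1L, 4), rep(2L, 3)),
    element = c("C", "N", "N", "N", "C", "O", "O"),
    mass = c(12.011, 14.007, 14.007, 14.007, 12.011, 15.999, 15.999),
    is_water = FALSE, stringsAsFactors = FALSE)
  xyz <- t(vapply(distances, function(d) {
    coords <- rbind(matrix(0, 4, 3),
                    matrix(rep(c(d, 0, 0), each = 3), 3, 3))
    as.vector(t(coords))
  }, numeric(21)))
  trajectory(atoms, xyz, dt_ps = 1)
}

# Hexamer condition whose 158-223 plant is bridged in chains A-D and set
# by `dwellsEF` in chains E and F.
make_condition <- function(dwellsEF, seed, n_frames = 4L) {
  plants <- default_bridge_plants()
  plants$dwell[plants$res_mobile == 223] <- c(1, 1, 1, 1, dwellsEF)
  build_hexamer(tiny_params(n_frames = n_frames, seed = seed,
                            bridge_plants = plants))
}

random_rotation <- function() {
  rotation_matrix(stats::rnorm(3), stats::runif(1, 0, 360))
}

# Apply a global rigid motion to every frame of a trajectory.
rigid_motion_traj <- function(traj, R, t) {
  xyz <- traj$xyz
  for (f in seq_len(nrow(xyz))) {
    fr <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    fr <- sweep(fr %*% t(R), 2L, t, `+`)
    xyz[f, ] <- as.vector(t(fr))
  }
  trajectory(traj$atoms, xyz, dt_ps = traj$dt_ps, source = traj$source)
}
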