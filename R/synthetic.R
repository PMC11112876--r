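# Synthetic hexameric four-helix-bundle pseudo-channel generator. Builds
# idealised protomers (Cα backbone helices plus the side-chain moiety
# atoms the metrics touch, plus single-oxygen waters), plants salt-bridge
# distances, helix tilts and pocket hydration with a ground-truth
# manifest, and applies seeded Gaussian jitter over frames. No physical
# realism is attempted: the geometry carries the statistical structure the
# analysis assumes, nothing more.

# Residue types given side-chain moiety atoms in the synthetic protomer.
.synth_special_residues <- c(
  `23` = "ARG", `33` = "ARG", `158` = "LYS", `162` = "GLU", `223` = "GLU"
)

# Small zero-centered offsets (Å) used to lay out moiety atoms around the
# moiety center so the mass-weighted COM lands exactly on the center.
.moiety_offsets <- function(atom_names, masses) {
  k <- length(atom_names)
  base <- rbind(
    c(1, 0, 0), c(-0.5, 0.866, 0), c(-0.5, -0.866, 0), c(0, 0, 1)
  )[seq_len(k), , drop = FALSE] * 0.6
  com <- colSums(base * masses) / sum(masses)
  sweep(base, 2L, com)
}

#' Rotation matrix about an arbitrary axis
#' @param axis length-3 vector (normalised internally).
#' @param deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_matrix <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  c1 <- cos(th); s1 <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  c1 * diag(3) + s1 * ux + (1 - c1) * (u %o% u)
}

#' Parameters of the synthetic hexamer generator
#'
#' Defaults describe a six-protomer channel of four ideal transmembrane
#' helices each (rise 1.5 Å/residue, 100°/residue, radius 2.3 Å, 22
#' residues per helix), protomers on a ring of radius 25 Å, TM1/TM3 and
#' TM2/TM4 helix axes 11 Å apart on the bundle diagonals, TM2/TM4
#' antiparallel to TM1/TM3. Residue numbering places the representative
#' residues 25/85/159/220 inside their segments (TM1 15-36, TM2 75-96,
#' TM3 144-165, TM4 210-231). Salt-bridge plants displace the mobile
#' residue's terminal moiety to an exact center-of-mass distance with
#' deterministic dwell scheduling (the first `ceiling(dwell * n_frames)`
#' frames are at the bridged distance). Pocket waters are placed uniformly
#' inside a 5 Å sphere around each protomer's pocket-Cα centroid; bulk
#' waters at least 7.5 Å from every pocket centroid.
#'
#' @param n_protomers number of protomers (6).
#' @param tm_length residues per TM helix (>= 11 so the representative
#'   residues stay inside their segments).
#' @param rise,twist,helix_radius ideal helix geometry (Å/residue,
#'   degrees/residue, Å).
#' @param ring_radius protomer placement radius (Å).
#' @param bundle_separation TM1-TM3 and TM2-TM4 axis separation (Å).
#' @param bridge_plants data.frame with columns `chain`, `res_fixed`,
#'   `res_mobile`, `distance`, `dwell` (see [default_bridge_plants]).
#' @param unbridged_distance moiety-COM distance used on non-dwell frames
#'   (Å).
#' @param dwell_mode `"deterministic"` (exact frame scheduling) or
#'   `"stochastic"` (each frame bridged independently with probability
#'   `dwell`).
#' @param tm_tilts optional named list, chain -> named degrees for
#'   `TM2`/`TM3`/`TM4`: tilts each helix about the membrane-plane x-axis
#'   through its own centroid (changes that protomer's inclinations).
#' @param n_pocket_waters planted waters per protomer pocket.
#' @param pocket_water_radius placement radius around the pocket centroid
#'   (Å; keep below the 6 Å counting cutoff).
#' @param n_bulk_waters background waters outside every pocket.
#' @param bulk_exclusion minimum bulk-water distance from any pocket
#'   centroid (Å; keep above the counting cutoff).
#' @param jitter_sigma per-coordinate Gaussian jitter s.d. (Å) applied to
#'   every atom in every frame.
#' @param n_frames,dt_ps frame count and spacing (ps).
#' @param seed integer seed fixing the full output bit-for-bit.
#' @return list of class `synthesis_params`.
#' @export
synthesis_params <- function(n_protomers = 6L, tm_length = 22L,
                             rise = 1.5, twist = 100, helix_radius = 2.3,
                             ring_radius = 25, bundle_separation = 11,
                             bridge_plants = default_bridge_plants(),
                             unbridged_distance = 6.0,
                             dwell_mode = c("deterministic", "stochastic"),
                             tm_tilts = NULL,
                             n_pocket_waters = 12L, pocket_water_radius = 5.0,
                             n_bulk_waters = 150L, bulk_exclusion = 7.5,
                             jitter_sigma = 0.15, n_frames = 50L, dt_ps = 1,
                             seed = 1L) {
  dwell_mode <- match.arg(dwell_mode)
  stopifnot(n_protomers == 6L, tm_length >= 11L, rise > 0, helix_radius > 0,
            ring_radius > 0, bundle_separation > 0, unbridged_distance > 0,
            n_pocket_waters >= 0L, pocket_water_radius > 0,
            n_bulk_waters >= 0L, bulk_exclusion > 0,
            jitter_sigma >= 0, n_frames >= 1L, dt_ps > 0)
  if (!is.null(bridge_plants)) {
    stopifnot(all(c("chain", "res_fixed", "res_mobile", "distance", "dwell")
                  %in% names(bridge_plants)))
    if (any(bridge_plants$dwell < 0 | bridge_plants$dwell > 1)) {
      stop("dwell fractions must lie in [0, 1]")
    }
    key <- paste(bridge_plants$chain, bridge_plants$res_mobile)
    if (anyDuplicated(key)) {
      stop("a residue may be the mobile end of at most one plant per chain")
    }
    both <- intersect(paste(bridge_plants$chain, bridge_plants$res_fixed), key)
    if (length(both)) {
      stop("residue(s) used as both fixed and mobile plant ends: ",
           paste(both, collapse = "; "))
    }
  }
  tm_starts <- c(TM1 = 15L, TM2 = 75L, TM3 = 144L, TM4 = 210L)
  segs <- lapply(tm_starts, function(s) c(s, s + tm_length - 1L))
  reps <- c(TM1 = 25, TM2 = 85, TM3 = 159, TM4 = 220)
  for (tm in names(segs)) {
    if (reps[[tm]] > segs[[tm]][2]) {
      stop("tm_length too short: representative residue ", reps[[tm]],
           " falls outside ", tm)
    }
  }
  structure(list(
    n_protomers = as.integer(n_protomers), tm_length = as.integer(tm_length),
    rise = rise, twist = twist, helix_radius = helix_radius,
    ring_radius = ring_radius, bundle_separation = bundle_separation,
    tm_segments = segs, representative_residues = reps,
    bridge_plants = bridge_plants, unbridged_distance = unbridged_distance,
    dwell_mode = dwell_mode, tm_tilts = tm_tilts,
    n_pocket_waters = as.integer(n_pocket_waters),
    pocket_water_radius = pocket_water_radius,
    n_bulk_waters = as.integer(n_bulk_waters),
    bulk_exclusion = bulk_exclusion,
    jitter_sigma = jitter_sigma, n_frames = as.integer(n_frames),
    dt_ps = dt_ps, seed = as.integer(seed)
  ), class = "synthesis_params")
}

#' Default salt-bridge plants: a wild-type-like pattern
#'
#' The 33-162 pair is bridged (3.5 Å, full dwell) in all six protomers;
#' the 158-223 pair is bridged in four of the six (chains A-D) and held at
#' the unbridged distance in chains E and F.
#'
#' @param chains protomer chain IDs.
#' @return data.frame of plants.
#' @export
default_bridge_plants <- function(chains = LETTERS[1:6]) {
  rbind(
    data.frame(chain = chains, res_fixed = 33, res_mobile = 162,
               distance = 3.5, dwell = 1, stringsAsFactors = FALSE),
    data.frame(chain = chains, res_fixed = 158, res_mobile = 223,
               distance = 3.5, dwell = c(1, 1, 1, 1, 0, 0),
               stringsAsFactors = FALSE)
  )
}

# Residues carrying moiety atoms, with elements and masses, for one type.
.moiety_atom_table <- function(resname) {
  atoms <- default_moiety_map()[[resname]]
  el <- infer_element(atoms)
  data.frame(atom_name = atoms, element = el,
             mass = atom_mass(el, atoms), stringsAsFactors = FALSE)
}

#' Build a synthetic hexamer trajectory with ground truth
#'
#' Assembles the six-protomer pseudo-channel described by `params`,
#' returning the jittered multi-frame [trajectory], a ground-truth
#' manifest holding exactly the values used to place atoms before jitter
#' (TM axis directions, representative-residue distances, inclinations,
#' per-plant distance schedules and realised occupancies, per-protomer
#' pocket water counts and centroids), and a matching
#' [channel_definition] whose pocket list contains the pocket residues the
#' model actually carries.
#'
#' @param params a [synthesis_params] object.
#' @return list of class `synthetic_hemichannel` with elements
#'   `trajectory`, `manifest`, `channel`.
#' @examples
#' b <- build_hexamer(synthesis_params(n_frames = 3, jitter_sigma = 0,
#'                                     seed = 7))
#' b$manifest$rep_distances[["A"]]
#' @export
build_hexamer <- function(params) {
  stopifnot(inherits(params, "synthesis_params"))
  p <- params
  set.seed(p$seed)
  chains <- LETTERS[seq_len(p$n_protomers)]
  a_side <- p$bundle_separation / sqrt(2)
  axis_xy <- list(TM1 = c(0, 0), TM2 = c(a_side, 0),
                  TM3 = c(a_side, a_side), TM4 = c(0, a_side))
  up <- c(TM1 = TRUE, TM2 = FALSE, TM3 = TRUE, TM4 = FALSE)
  twist_rad <- p$twist * pi / 180

  atoms_list <- list()
  coords_list <- list()
  manifest_axes <- list(); manifest_dist <- list(); manifest_incl <- list()
  pocket_centroids <- list()
  moiety_center <- list()   # key "chain:resno" -> default moiety center
  moiety_rows <- list()     # key -> atom row indices in the global table
  serial <- 0L

  for (ci in seq_along(chains)) {
    ch <- chains[ci]
    phi <- 60 * (ci - 1)
    Rz <- rotation_matrix(c(0, 0, 1), phi)
    shift <- p$ring_radius * c(cos(phi * pi / 180), sin(phi * pi / 180), 0)
    tilts <- p$tm_tilts[[ch]]
    dirs <- matrix(NA_real_, 3, 4,
                   dimnames = list(NULL, paste0("TM", 1:4)))
    rep_ca <- list()
    ch_rows <- list(); ch_xyz <- list()
    for (tm in paste0("TM", 1:4)) {
      seg <- p$tm_segments[[tm]]
      resnos <- seq(seg[1], seg[2])
      ir <- p$representative_residues[[tm]] - seg[1]
      i <- seq_along(resnos) - 1L
      sgn <- if (up[[tm]]) 1 else -1
      theta <- sgn * (i - ir) * twist_rad
      ca <- cbind(axis_xy[[tm]][1] + p$helix_radius * cos(theta),
                  axis_xy[[tm]][2] + p$helix_radius * sin(theta),
                  sgn * (i - ir) * p$rise)
      direction <- c(0, 0, sgn)
      # a finite helix's total-least-squares axis deviates slightly from
      # its geometric axis (the sampled phases are unbalanced); rotate the
      # helix so its TLS axis coincides with the intended direction, which
      # makes the manifest an exact fixed point of the analysis at zero
      # jitter
      a0 <- fit_axis(ca)$direction
      cosang <- max(-1, min(1, sum(a0 * direction)))
      if (cosang < 1 - 1e-15) {
        rot_axis <- c(a0[2] * direction[3] - a0[3] * direction[2],
                      a0[3] * direction[1] - a0[1] * direction[3],
                      a0[1] * direction[2] - a0[2] * direction[1])
        if (sqrt(sum(rot_axis^2)) > 1e-12) {
          Rc <- rotation_matrix(rot_axis, acos(cosang) * 180 / pi)
          cen0 <- colMeans(ca)
          ca <- sweep(sweep(ca, 2L, cen0) %*% t(Rc), 2L, cen0, `+`)
        }
      }
      # per-helix tilt about the membrane-plane x-axis through the helix
      # centroid (protomer-local frame)
      tdeg <- if (!is.null(tilts) && tm %in% names(tilts)) tilts[[tm]] else 0
      if (tdeg != 0) {
        Rt <- rotation_matrix(c(1, 0, 0), tdeg)
        cen <- colMeans(ca)
        ca <- sweep(sweep(ca, 2L, cen) %*% t(Rt), 2L, cen, `+`)
        direction <- as.numeric(Rt %*% direction)
      }
      # place into the lab frame
      ca_lab <- sweep(ca %*% t(Rz), 2L, shift, `+`)
      dirs[, tm] <- as.numeric(Rz %*% direction)
      rep_ca[[tm]] <- ca_lab[ir + 1L, ]
      for (k in seq_along(resnos)) {
        rn <- resnos[k]
        resname <- .synth_special_residues[as.character(rn)]
        if (is.na(resname)) resname <- "ALA"
        serial <- serial + 1L
        ch_rows[[length(ch_rows) + 1L]] <- data.frame(
          serial = serial, atom_name = "CA", residue_name = resname,
          chain_id = ch, residue_number = rn, element = "C",
          mass = atom_mass("C", "CA"), is_water = FALSE,
          stringsAsFactors = FALSE)
        ch_xyz[[length(ch_xyz) + 1L]] <- ca_lab[k, , drop = FALSE]
        if (!is.na(.synth_special_residues[as.character(rn)])) {
          mt <- .moiety_atom_table(resname)
          # default moiety center: 1.2 Å radially outward from the helix
          # axis at the Cα
          ax_lab <- as.numeric(Rz %*% c(axis_xy[[tm]], 0)) + shift
          radial <- ca_lab[k, ] - c(ax_lab[1], ax_lab[2], ca_lab[k, 3])
          radial <- radial / sqrt(sum(radial^2))
          center <- ca_lab[k, ] + 1.2 * radial
          key <- paste0(ch, ":", rn)
          moiety_center[[key]] <- center
          offs <- .moiety_offsets(mt$atom_name, mt$mass)
          rows <- integer(nrow(mt))
          for (j in seq_len(nrow(mt))) {
            serial <- serial + 1L
            ch_rows[[length(ch_rows) + 1L]] <- data.frame(
              serial = serial, atom_name = mt$atom_name[j],
              residue_name = resname, chain_id = ch, residue_number = rn,
              element = mt$element[j], mass = mt$mass[j], is_water = FALSE,
              stringsAsFactors = FALSE)
            ch_xyz[[length(ch_xyz) + 1L]] <-
              matrix(center + offs[j, ], nrow = 1L)
            rows[j] <- length(ch_rows)  # chain-local; fixed up below
          }
          moiety_rows[[key]] <- rows    # chain-local indices, fixed below
        }
      }
    }
    n_before <- sum(vapply(atoms_list, nrow, integer(1)))
    for (key in names(moiety_rows)) {
      if (startsWith(key, paste0(ch, ":")) &&
          max(moiety_rows[[key]]) <= length(ch_rows)) {
        moiety_rows[[key]] <- moiety_rows[[key]] + n_before
      }
    }
    atoms_list[[ci]] <- do.call(rbind, ch_rows)
    coords_list[[ci]] <- do.call(rbind, ch_xyz)
    manifest_axes[[ch]] <- dirs
    manifest_dist[[ch]] <- c(
      `TM1-TM3` = sqrt(sum((rep_ca$TM1 - rep_ca$TM3)^2)),
      `TM2-TM4` = sqrt(sum((rep_ca$TM2 - rep_ca$TM4)^2)))
    manifest_incl[[ch]] <- vapply(c("TM2", "TM3", "TM4"), function(tm) {
      d <- sum(dirs[, "TM1"] * dirs[, tm])
      acos(max(-1, min(1, d))) * 180 / pi
    }, numeric(1))
  }

  atoms <- do.call(rbind, atoms_list)
  base <- do.call(rbind, coords_list)
  rownames(atoms) <- NULL

  # pocket centroids from the built Cα positions (pre-water, pre-jitter)
  pocket_present <- intersect(.default_pocket_residues,
                              unlist(lapply(p$tm_segments,
                                            function(s) seq(s[1], s[2]))))
  for (ch in chains) {
    sel <- which(atoms$chain_id == ch & atoms$atom_name == "CA" &
                 atoms$residue_number %in% pocket_present)
    pocket_centroids[[ch]] <- colMeans(base[sel, , drop = FALSE])
  }

  # waters: planted pocket waters per protomer, then bulk waters
  water_xyz <- list(); water_rows <- list(); pocket_water_idx <- list()
  wres <- 0L
  for (ch in chains) {
    cen <- pocket_centroids[[ch]]
    got <- 0L; pts <- matrix(numeric(0), 0, 3)
    while (got < p$n_pocket_waters) {
      cand <- stats::runif(3, -1, 1) * p$pocket_water_radius
      if (sum(cand^2) <= p$pocket_water_radius^2) {
        pts <- rbind(pts, cen + cand); got <- got + 1L
      }
    }
    first <- wres + 1L
    for (k in seq_len(nrow(pts))) {
      wres <- wres + 1L; serial <- serial + 1L
      water_rows[[wres]] <- data.frame(
        serial = serial, atom_name = "O", residue_name = "HOH",
        chain_id = "W", residue_number = wres, element = "O",
        mass = atom_mass("O", "O"), is_water = TRUE, stringsAsFactors = FALSE)
      water_xyz[[wres]] <- matrix(pts[k, ], nrow = 1L)
    }
    pocket_water_idx[[ch]] <- if (p$n_pocket_waters > 0) seq(first, wres)
                              else integer(0)
  }
  if (p$n_bulk_waters > 0) {
    lo <- apply(base, 2L, min) - 5; hi <- apply(base, 2L, max) + 5
    cents <- do.call(rbind, pocket_centroids)
    got <- 0L
    while (got < p$n_bulk_waters) {
      cand <- lo + stats::runif(3) * (hi - lo)
      d2 <- rowSums(sweep(cents, 2L, cand)^2)
      if (min(d2) >= p$bulk_exclusion^2) {
        wres <- wres + 1L; serial <- serial + 1L; got <- got + 1L
        water_rows[[wres]] <- data.frame(
          serial = serial, atom_name = "O", residue_name = "HOH",
          chain_id = "W", residue_number = wres, element = "O",
          mass = atom_mass("O", "O"), is_water = TRUE,
          stringsAsFactors = FALSE)
        water_xyz[[wres]] <- matrix(cand, nrow = 1L)
      }
    }
  }
  n_prot_atoms <- nrow(atoms)
  if (wres > 0) {
    atoms <- rbind(atoms, do.call(rbind, water_rows))
    base <- rbind(base, do.call(rbind, water_xyz))
  }
  for (ch in chains) {
    pocket_water_idx[[ch]] <- pocket_water_idx[[ch]] + n_prot_atoms
  }

  # plant schedules: per-frame moiety-COM distances for each plant
  plants <- p$bridge_plants
  schedules <- list()
  if (!is.null(plants) && nrow(plants)) {
    for (q in seq_len(nrow(plants))) {
      pl <- plants[q, ]
      n_bridged <- as.integer(ceiling(pl$dwell * p$n_frames))
      bridged <- if (p$dwell_mode == "deterministic") {
        seq_len(p$n_frames) <= n_bridged
      } else {
        stats::runif(p$n_frames) < pl$dwell
      }
      schedules[[q]] <- ifelse(bridged, pl$distance, p$unbridged_distance)
    }
  }

  # assemble frames: static base, moving plant moieties, then jitter
  nat <- nrow(atoms)
  xyz <- matrix(NA_real_, p$n_frames, 3L * nat)
  for (f in seq_len(p$n_frames)) {
    fr <- base
    if (!is.null(plants) && nrow(plants)) {
      for (q in seq_len(nrow(plants))) {
        pl <- plants[q, ]
        kf <- paste0(pl$chain, ":", pl$res_fixed)
        km <- paste0(pl$chain, ":", pl$res_mobile)
        if (is.null(moiety_center[[kf]]) || is.null(moiety_center[[km]])) {
          stop("plant references residue without moiety atoms: ",
               kf, " or ", km)
        }
        v <- moiety_center[[km]] - moiety_center[[kf]]
        v <- v / sqrt(sum(v^2))
        new_center <- moiety_center[[kf]] + schedules[[q]][f] * v
        rows <- moiety_rows[[km]]
        old_center <- moiety_center[[km]]
        fr[rows, ] <- sweep(sweep(base[rows, , drop = FALSE], 2L,
                                  old_center), 2L, new_center, `+`)
      }
    }
    if (p$jitter_sigma > 0) {
      fr <- fr + matrix(stats::rnorm(3L * nat, 0, p$jitter_sigma), nat, 3L)
    }
    xyz[f, ] <- as.vector(t(fr))
  }

  traj <- trajectory(atoms, xyz, dt_ps = p$dt_ps,
                     source = sprintf("synthetic hexamer (seed %d)", p$seed))

  plant_manifest <- NULL
  if (!is.null(plants) && nrow(plants)) {
    plant_manifest <- plants
    plant_manifest$occupancy <- vapply(seq_len(nrow(plants)), function(q) {
      mean(schedules[[q]] <= 4.0)
    }, numeric(1))
    plant_manifest$schedule <- I(schedules)
  }

  manifest <- structure(list(
    params = p,
    tm_axes = manifest_axes,
    rep_distances = manifest_dist,
    inclinations = manifest_incl,
    plants = plant_manifest,
    pocket_counts = stats::setNames(rep(p$n_pocket_waters, length(chains)),
                                    chains),
    pocket_centroids = pocket_centroids,
    pocket_water_idx = pocket_water_idx,
    pocket_residues_present = pocket_present,
    jitter_sigma = p$jitter_sigma,
    seed = p$seed
  ), class = "ground_truth_manifest")

  channel <- channel_definition(
    protomer_chains = chains,
    tm_segments = p$tm_segments,
    representative_residues = p$representative_residues,
    pocket_residues = pocket_present,
    bridge_cutoff = 4.0, water_cutoff = 6.0
  )

  structure(list(trajectory = traj, manifest = manifest, channel = channel),
            class = "synthetic_hemichannel")
}

#' @export
print.synthetic_hemichannel <- function(x, ...) {
  cat("synthetic hemichannel fixture\n")
  print(x$trajectory)
  invisible(x)
}

#' Rigidly tilt one protomer of a synthetic hexamer
#'
#' Rotates every atom of the protomer chain (and its planted pocket
#' waters, which travel with it) by `tilt_deg` about a membrane-plane axis
#' through the protomer's per-frame atom centroid, in every frame. A rigid
#' rotation leaves all intra-protomer metrics (TM-TM distances,
#' inclinations, bridge distances) unchanged; the manifest's TM axis
#' directions and pocket centroid are rotated accordingly. Successive
#' tilts about the same axis compose additively.
#'
#' @param x a `synthetic_hemichannel` (from [build_hexamer]) or a plain
#'   [trajectory].
#' @param protomer chain ID to tilt.
#' @param tilt_deg rotation angle in degrees.
#' @param axis membrane-plane rotation axis (default the x-axis).
#' @return object of the same class as `x`, tilted.
#' @export
perturb_protomer <- function(x, protomer, tilt_deg, axis = c(1, 0, 0)) {
  traj <- if (inherits(x, "synthetic_hemichannel")) x$trajectory else x
  stopifnot(inherits(traj, "trajectory"))
  idx <- which(traj$atoms$chain_id == protomer)
  if (length(idx) == 0L) stop("unknown protomer chain: ", protomer)
  if (inherits(x, "synthetic_hemichannel")) {
    idx <- c(idx, x$manifest$pocket_water_idx[[protomer]])
  }
  R <- rotation_matrix(axis, tilt_deg)
  xyz <- traj$xyz
  for (f in seq_len(nrow(xyz))) {
    fr <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    cen <- colMeans(fr[idx, , drop = FALSE])
    fr[idx, ] <- sweep(sweep(fr[idx, , drop = FALSE], 2L, cen) %*% t(R),
                       2L, cen, `+`)
    xyz[f, ] <- as.vector(t(fr))
  }
  out_traj <- trajectory(traj$atoms, xyz, dt_ps = traj$dt_ps,
                         source = traj$source)
  if (!inherits(x, "synthetic_hemichannel")) return(out_traj)
  man <- x$manifest
  man$tm_axes[[protomer]] <- R %*% man$tm_axes[[protomer]]
  x$trajectory <- out_traj
  x$manifest <- man
  x
}
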