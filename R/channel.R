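# Hemichannel metrics: salt-bridge occupancy from terminal-moiety centers
# of mass, TM representative-residue distances, TM inclination angles, and
# intracellular-pocket water counts.

#' Default terminal-moiety atom map
#'
#' Atom names of the charged/polar side-chain end group used for
#' salt-bridge distances: guanidinium for Arg (CZ, NH1, NH2, NE),
#' carboxylate for Glu (CD, OE1, OE2) and Asp (CG, OD1, OD2), amide for
#' Gln (CD, OE1, NE2), terminal amine for Lys (NZ).
#'
#' @return named list mapping residue name to atom-name character vector.
#' @export
default_moiety_map <- function() {
  list(
    ARG = c("CZ", "NH1", "NH2", "NE"),
    GLU = c("CD", "OE1", "OE2"),
    GLN = c("CD", "OE1", "NE2"),
    LYS = "NZ",
    ASP = c("CG", "OD1", "OD2")
  )
}

# The 30 pocket-lining residue numbers (intracellular pocket definition).
.default_pocket_residues <- c(
  9, 12, 13, 16, 18, 23, 26, 27, 30, 33, 34,
  81, 85, 86, 88, 89, 92, 93,
  148, 151, 154, 155, 158, 159, 162,
  216, 219, 220, 223, 227
)

#' Define the channel being analysed
#'
#' Collects the structural conventions every metric needs: the six
#' protomer chains, the four transmembrane segment ranges, the residue
#' representative of each TM (the one closest to the TM's center of mass),
#' the pocket-lining residue list, and the distance cutoffs.
#'
#' @param protomer_chains ordered chain IDs, one per protomer (6 chains).
#' @param tm_segments named list `TM1`..`TM4` of inclusive residue-number
#'   ranges `c(first, last)`. May be `NULL` if no TM-axis metric is used;
#'   there is no universal default, the ranges are construct-specific.
#' @param representative_residues named numeric vector with entries
#'   `TM1`, `TM2`, `TM3`, `TM4`. Defaults 25/85/159/220.
#' @param pocket_residues residue numbers lining the intracellular pocket
#'   (default: the 30-residue list of the connexin50 pocket).
#' @param bridge_cutoff salt-bridge moiety-COM distance cutoff (Å,
#'   default 4.0).
#' @param water_cutoff pocket hydration distance cutoff (Å, default 6.0).
#' @param moiety_map terminal-moiety atom map, see [default_moiety_map].
#' @return list of class `channel_definition`.
#' @export
channel_definition <- function(protomer_chains = LETTERS[1:6],
                               tm_segments = NULL,
                               representative_residues =
                                 c(TM1 = 25, TM2 = 85, TM3 = 159, TM4 = 220),
                               pocket_residues = .default_pocket_residues,
                               bridge_cutoff = 4.0,
                               water_cutoff = 6.0,
                               moiety_map = default_moiety_map()) {
  if (length(protomer_chains) != 6L) stop("a hexamer needs 6 protomer chains")
  if (bridge_cutoff <= 0 || water_cutoff <= 0) stop("cutoffs must be positive")
  if (!is.null(tm_segments)) {
    tms <- paste0("TM", 1:4)
    if (!all(tms %in% names(tm_segments))) {
      stop("tm_segments must name TM1..TM4")
    }
    tm_segments <- tm_segments[tms]
    rng <- lapply(tm_segments, function(r) seq(r[1], r[2]))
    if (anyDuplicated(unlist(rng))) stop("TM segment ranges must be disjoint")
    for (tm in tms) {
      rr <- representative_residues[[tm]]
      if (!(rr >= tm_segments[[tm]][1] && rr <= tm_segments[[tm]][2])) {
        stop("representative residue of ", tm, " (", rr,
             ") lies outside its segment")
      }
    }
  }
  structure(list(
    protomer_chains = protomer_chains,
    tm_segments = tm_segments,
    representative_residues = representative_residues,
    pocket_residues = sort(unique(pocket_residues)),
    bridge_cutoff = bridge_cutoff,
    water_cutoff = water_cutoff,
    moiety_map = moiety_map
  ), class = "channel_definition")
}

#' Write / read a channel definition as a JSON config file
#'
#' @param channel a [channel_definition].
#' @param path file path for the JSON config.
#' @return `path` invisibly (write) or a [channel_definition] (read).
#' @export
write_channel_config <- function(channel, path) {
  stopifnot(inherits(channel, "channel_definition"))
  x <- unclass(channel)
  x$representative_residues <- as.list(x$representative_residues)
  jsonlite::write_json(x, path, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_channel_config
#' @export
read_channel_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  tm <- if (length(x$tm_segments)) lapply(x$tm_segments, as.numeric) else NULL
  channel_definition(
    protomer_chains = x$protomer_chains,
    tm_segments = tm,
    representative_residues = unlist(x$representative_residues),
    pocket_residues = as.numeric(x$pocket_residues),
    bridge_cutoff = as.numeric(x$bridge_cutoff),
    water_cutoff = as.numeric(x$water_cutoff),
    moiety_map = lapply(x$moiety_map, as.character)
  )
}

# Resolve the terminal-moiety atom indices of one residue; errors name the
# residue when its type is unmapped or moiety atoms are missing.
.moiety_indices <- function(traj, channel, chain, resno) {
  sel <- select_atoms(traj, chain = chain, residue_numbers = resno)
  if (length(sel) == 0L) {
    stop("residue ", chain, ":", resno, " not present in trajectory")
  }
  resname <- unique(traj$atoms$residue_name[sel])[1]
  atoms <- channel$moiety_map[[resname]]
  if (is.null(atoms)) {
    stop("residue ", chain, ":", resno, " (", resname,
         ") has no terminal-moiety definition")
  }
  idx <- sel[traj$atoms$atom_name[sel] %in% atoms]
  found <- traj$atoms$atom_name[idx]
  if (!all(atoms %in% found)) {
    stop("residue ", chain, ":", resno, " is missing moiety atom(s): ",
         paste(setdiff(atoms, found), collapse = ", "))
  }
  idx
}

#' Salt-bridge distance series and occupancy for one residue pair
#'
#' Per-frame distance between the mass-weighted centers of the terminal
#' moieties of the two residues (guanidinium/carboxylate/amide/amine atom
#' sets from the channel's moiety map). Occupancy is the fraction of
#' frames at interacting distance (<= `bridge_cutoff`, default 4 Å); the
#' pair is classified as bridged when occupancy >= `occupancy_threshold`.
#'
#' @param traj a [trajectory].
#' @param channel a [channel_definition].
#' @param resA,resB residues as `list(chain =, resno =)` or a
#'   `c(chain, resno)` pair; they may sit on the same or different chains.
#' @param occupancy_threshold classification threshold on occupancy
#'   (default 0.5).
#' @return list of class `bridge_report`: `pair`, `series` (Å per frame),
#'   `occupancy`, `bridged`, and `summary` (mean, sd, median).
#' @export
saltbridge_series <- function(traj, channel, resA, resB,
                              occupancy_threshold = 0.5) {
  pa <- .as_residue_ref(resA); pb <- .as_residue_ref(resB)
  ia <- .moiety_indices(traj, channel, pa$chain, pa$resno)
  ib <- .moiety_indices(traj, channel, pb$chain, pb$resno)
  d <- pair_distance_series(traj, ia, ib, mode = "com")
  occ <- mean(d <= channel$bridge_cutoff)
  structure(list(
    pair = list(chainA = pa$chain, residueA = pa$resno,
                chainB = pb$chain, residueB = pb$resno),
    series = d,
    occupancy = occ,
    bridged = occ >= occupancy_threshold,
    summary = c(mean = mean(d), sd = stats::sd(d), median = stats::median(d))
  ), class = "bridge_report")
}

.as_residue_ref <- function(x) {
  if (is.list(x)) list(chain = x$chain, resno = as.numeric(x$resno))
  else list(chain = as.character(x[1]), resno = as.numeric(x[2]))
}

#' @export
print.bridge_report <- function(x, ...) {
  cat(sprintf("salt bridge %s:%d - %s:%d  occupancy %.3f (%s), mean %.2f Å\n",
              x$pair$chainA, x$pair$residueA, x$pair$chainB, x$pair$residueB,
              x$occupancy, ifelse(x$bridged, "bridged", "not bridged"),
              x$summary["mean"]))
  invisible(x)
}

#' Count protomers in which a residue pair forms a salt bridge
#'
#' Applies [saltbridge_series] to the pair within each protomer chain and
#' counts the chains classified as bridged (e.g. "4 of 6 protomers").
#' Raising the bridge cutoff never decreases the count.
#'
#' @param traj a [trajectory].
#' @param channel a [channel_definition].
#' @param pair numeric residue-number pair, e.g. `c(158, 223)`.
#' @param occupancy_threshold passed to [saltbridge_series].
#' @return integer in `[0, 6]`.
#' @export
bridged_protomer_count <- function(traj, channel, pair,
                                   occupancy_threshold = 0.5) {
  sum(vapply(channel$protomer_chains, function(ch) {
    saltbridge_series(traj, channel,
                      list(chain = ch, resno = pair[1]),
                      list(chain = ch, resno = pair[2]),
                      occupancy_threshold = occupancy_threshold)$bridged
  }, logical(1)))
}

# Cα index of one residue; hard error when absent (used for the
# representative-residue metrics which the analysis names exactly).
.ca_index <- function(traj, chain, resno, what) {
  i <- select_atoms(traj, chain = chain, residue_numbers = resno,
                    atom_names = "CA")
  if (length(i) != 1L) {
    stop("missing Cα for ", what, " residue ", chain, ":", resno)
  }
  i
}

#' Inter-TM distance from representative residues
#'
#' Per-frame Euclidean distance between the Cα atoms of the two
#' representative residues of a TM pair within one protomer (residues
#' 25/159 for TM1-TM3 and 85/220 for TM2-TM4 by default; the
#' representatives are the residues closest to each TM's center of mass).
#'
#' @param traj a [trajectory].
#' @param channel a [channel_definition].
#' @param protomer chain ID of the protomer.
#' @param pair `"TM1-TM3"` or `"TM2-TM4"`.
#' @return numeric vector of distances (Å), one per frame.
#' @export
tm_distance <- function(traj, channel, protomer,
                        pair = c("TM1-TM3", "TM2-TM4")) {
  pair <- match.arg(pair)
  tms <- strsplit(pair, "-", fixed = TRUE)[[1]]
  rr <- channel$representative_residues
  ia <- .ca_index(traj, protomer, rr[[tms[1]]], tms[1])
  ib <- .ca_index(traj, protomer, rr[[tms[2]]], tms[2])
  pair_distance_series(traj, ia, ib, mode = "single")
}

# Ordered Cα indices of one TM segment in one protomer.
.tm_ca_indices <- function(traj, channel, protomer, tm) {
  if (is.null(channel$tm_segments)) {
    stop("channel definition has no tm_segments; TM-axis metrics need them")
  }
  rng <- channel$tm_segments[[tm]]
  idx <- select_atoms(traj, chain = protomer,
                      residue_numbers = seq(rng[1], rng[2]),
                      atom_names = "CA")
  idx[order(traj$atoms$residue_number[idx])]
}

#' Inclination of a TM helix relative to TM1
#'
#' Per-frame angle between the best-fit straight line (total least
#' squares) through the Cα atoms of TM1 and that of the requested TM,
#' within one protomer. Axes are oriented N-terminus to C-terminus, so a
#' topologically antiparallel helix reads near 180°.
#'
#' @param traj a [trajectory].
#' @param channel a [channel_definition] with `tm_segments`.
#' @param protomer chain ID.
#' @param tm `"TM2"`, `"TM3"` or `"TM4"`.
#' @return numeric vector of angles (degrees), one per frame.
#' @export
tm_inclination <- function(traj, channel, protomer,
                           tm = c("TM2", "TM3", "TM4")) {
  tm <- match.arg(tm)
  i1 <- .tm_ca_indices(traj, channel, protomer, "TM1")
  ik <- .tm_ca_indices(traj, channel, protomer, tm)
  if (length(i1) < 3L || length(ik) < 3L) {
    stop("TM segment with fewer than 3 Cα atoms in protomer ", protomer)
  }
  vapply(seq_len(n_frames(traj)), function(k) {
    axis_angle(fit_axis(frame_coords(traj, k, i1)),
               fit_axis(frame_coords(traj, k, ik)))
  }, numeric(1))
}

# Pocket Cα indices for one protomer; warns once per call about
# pocket-list residues absent from the model, errors if none are present.
.pocket_ca_indices <- function(traj, channel, protomer, quiet = FALSE) {
  idx <- select_atoms(traj, chain = protomer,
                      residue_numbers = channel$pocket_residues,
                      atom_names = "CA")
  present <- traj$atoms$residue_number[idx]
  missing <- setdiff(channel$pocket_residues, present)
  if (length(idx) == 0L) {
    stop("no pocket residues present in protomer ", protomer)
  }
  if (length(missing) && !quiet) {
    warning("protomer ", protomer, ": pocket residue(s) ",
            paste(missing, collapse = ", "),
            " absent; centroid uses the ", length(idx), " present")
  }
  idx
}

#' Water count inside the intracellular pocket
#'
#' For each frame, the pocket centroid is the center of mass of the Cα
#' atoms of the pocket-lining residues of the protomer (recomputed per
#' frame by default), and the count is the number of water molecules whose
#' oxygen lies within `water_cutoff` (<= 6.0 Å by default; the boundary is
#' included). Waters are identified by residue name; one oxygen per
#' molecule is counted, hydrogens being irrelevant to the criterion.
#'
#' @param traj a [trajectory].
#' @param channel a [channel_definition].
#' @param protomer chain ID.
#' @param fixed_centroid if `TRUE`, the centroid of frame 1 is reused for
#'   all frames instead of being recomputed.
#' @param quiet suppress the missing-pocket-residue warning.
#' @return integer vector of counts, one per frame.
#' @export
pocket_water_count <- function(traj, channel, protomer,
                               fixed_centroid = FALSE, quiet = FALSE) {
  pidx <- .pocket_ca_indices(traj, channel, protomer, quiet = quiet)
  widx <- select_atoms(traj, water = TRUE)
  ox <- widx[infer_element(traj$atoms$atom_name[widx]) == "O"]
  pm <- traj$atoms$mass[pidx]
  cen1 <- center_of_mass(frame_coords(traj, 1L, pidx), pm)
  vapply(seq_len(n_frames(traj)), function(k) {
    cen <- if (fixed_centroid) cen1
           else center_of_mass(frame_coords(traj, k, pidx), pm)
    if (length(ox) == 0L) return(0L)
    w <- frame_coords(traj, k, ox)
    d2 <- (w[, 1] - cen[1])^2 + (w[, 2] - cen[2])^2 + (w[, 3] - cen[3])^2
    sum(d2 <= channel$water_cutoff^2)
  }, integer(1))
}

#' Pocket hydration series over protomers and replicas
#'
#' Computes [pocket_water_count] for every protomer of every replica
#' trajectory. Returns per-replica/protomer/frame counts in tidy form, the
#' pooled distribution over all frames, protomers and replicas, and the
#' per-frame mean and sample standard deviation across replicas (of the
#' protomer-summed count), mirroring a time-course "mean ± s.d. of the
#' replicas" presentation.
#'
#' @param trajs a [trajectory] or list of replica trajectories with
#'   identical frame counts.
#' @param channel a [channel_definition].
#' @param quiet suppress missing-pocket-residue warnings.
#' @return list of class `count_series`: `table` (data.frame with columns
#'   replica, protomer, frame, time_ps, count), `pooled` (integer vector),
#'   `per_frame_mean`, `per_frame_sd` (across replicas, protomer-averaged
#'   count per frame).
#' @export
pocket_water_series <- function(trajs, channel, quiet = FALSE) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  nf <- vapply(trajs, n_frames, integer(1))
  if (length(unique(nf)) != 1L) stop("replicas must have equal frame counts")
  rows <- list()
  for (r in seq_along(trajs)) {
    tt <- frame_times(trajs[[r]])
    for (ch in channel$protomer_chains) {
      cnt <- pocket_water_count(trajs[[r]], channel, ch, quiet = quiet)
      rows[[length(rows) + 1L]] <- data.frame(
        replica = r, protomer = ch, frame = seq_along(cnt),
        time_ps = tt, count = cnt, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  # per-frame protomer-mean count within each replica, then mean/sd across
  # replicas (sample s.d., n - 1)
  per_rep <- sapply(seq_along(trajs), function(r) {
    sub <- tab[tab$replica == r, ]
    tapply(sub$count, sub$frame, mean)
  })
  per_rep <- matrix(per_rep, nrow = nf[1])
  structure(list(
    table = tab,
    pooled = tab$count,
    per_frame_mean = rowMeans(per_rep),
    per_frame_sd = apply(per_rep, 1L, stats::sd)
  ), class = "count_series")
}
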