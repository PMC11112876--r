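# Coordinate geometry: centers of mass, Kabsch superposition, RMSD/RMSF,
# total-least-squares axis fitting, inter-axis angles, pair distances.

#' Mass-weighted center of mass
#'
#' @param coords n x 3 matrix of positions (Å).
#' @param masses numeric vector of length n, all > 0. Defaults to uniform.
#' @return length-3 numeric vector.
#' @examples
#' center_of_mass(rbind(c(0, 0, 0), c(0, 0, 2)))
#' @export
center_of_mass <- function(coords, masses = NULL) {
  coords <- rbind(coords)
  if (nrow(coords) == 0L) stop("center_of_mass of an empty selection")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (any(masses <= 0)) stop("masses must be positive")
  colSums(coords * masses) / sum(masses)
}

#' Optimal superposition of two point sets (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimising the (weighted)
#' RMSD between `mobile` and `reference`. The SVD determinant correction is
#' applied, so a reflection is never returned even for mirror-image inputs.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @param weights optional positive weights of length n.
#' @return list with `rotation` (3 x 3, det +1), `translation` (length 3)
#'   and `rmsd` (Å). The fitted mobile coordinates are
#'   `mobile %*% t(rotation) + translation` (row-wise).
#' @export
kabsch_superpose <- function(mobile, reference, weights = NULL) {
  mobile <- rbind(mobile); reference <- rbind(reference)
  if (nrow(mobile) != nrow(reference)) {
    stop("mobile and reference must have the same number of points")
  }
  if (nrow(mobile) < 3L) stop("at least 3 points are required")
  n <- nrow(mobile)
  w <- if (is.null(weights)) rep(1, n) else weights
  if (length(w) != n || any(w <= 0)) stop("weights must be positive, length n")
  w <- w / sum(w)
  cm_mob <- colSums(mobile * w)
  cm_ref <- colSums(reference * w)
  P <- sweep(mobile, 2L, cm_mob)
  Q <- sweep(reference, 2L, cm_ref)
  C <- t(P) %*% (Q * w)
  s <- svd(C)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((fitted - Q)^2)))
  list(rotation = R, translation = as.numeric(cm_ref - R %*% cm_mob),
       rmsd = rmsd)
}

#' Apply a superposition to coordinates
#' @param coords n x 3 matrix.
#' @param fit result of [kabsch_superpose].
#' @return transformed n x 3 matrix.
#' @keywords internal
apply_superposition <- function(coords, fit) {
  sweep(rbind(coords) %*% t(fit$rotation), 2L, fit$translation, `+`)
}

#' Per-frame RMSD against a reference frame
#'
#' Each frame's selected atoms are superposed (Kabsch, uniform weights)
#' onto the same selection in the reference frame; the RMSD over that
#' selection after superposition is returned. The value at the reference
#' frame is 0 by construction.
#'
#' @param traj a [trajectory].
#' @param idx integer atom indices of the selection (e.g. Cα atoms from
#'   [select_atoms]); must contain >= 3 atoms.
#' @param reference_frame 1-based index of the reference frame.
#' @return numeric vector, one RMSD (Å) per frame.
#' @export
rmsd_series <- function(traj, idx, reference_frame = 1L) {
  if (reference_frame < 1L || reference_frame > n_frames(traj)) {
    stop("reference frame index out of range")
  }
  if (length(idx) < 3L) stop("selection must contain at least 3 atoms")
  ref <- frame_coords(traj, reference_frame, idx)
  vapply(seq_len(n_frames(traj)), function(k) {
    kabsch_superpose(frame_coords(traj, k, idx), ref)$rmsd
  }, numeric(1))
}

#' Per-atom root mean square fluctuation
#'
#' Two-pass alignment: frames are first superposed onto the selection in
#' frame 1, the mean structure is computed, all frames are re-aligned to
#' that mean, and the RMSF of each selected atom is the root mean square
#' distance from its (re-computed) mean position. Uniform weights over the
#' selection; for a Cα selection this is the conventional per-residue
#' fluctuation profile.
#'
#' @param traj a [trajectory] with >= 2 frames.
#' @param idx integer atom indices of the selection (>= 3 atoms).
#' @return numeric vector of RMSF values (Å), one per selected atom, named
#'   `chain:residue_number`.
#' @export
rmsf_per_residue <- function(traj, idx) {
  if (n_frames(traj) < 2L) stop("RMSF requires at least 2 frames")
  if (length(idx) < 3L) stop("selection must contain at least 3 atoms")
  nf <- n_frames(traj)
  ref <- frame_coords(traj, 1L, idx)
  aligned <- lapply(seq_len(nf), function(k) {
    x <- frame_coords(traj, k, idx)
    apply_superposition(x, kabsch_superpose(x, ref))
  })
  mean_struct <- Reduce(`+`, aligned) / nf
  aligned2 <- lapply(seq_len(nf), function(k) {
    x <- frame_coords(traj, k, idx)
    apply_superposition(x, kabsch_superpose(x, mean_struct))
  })
  mean2 <- Reduce(`+`, aligned2) / nf
  sq <- Reduce(`+`, lapply(aligned2, function(x) rowSums((x - mean2)^2))) / nf
  out <- sqrt(sq)
  names(out) <- paste0(traj$atoms$chain_id[idx], ":",
                       traj$atoms$residue_number[idx])
  out
}

#' Total-least-squares line through ordered points
#'
#' Fits the best straight line through >= 3 ordered points as the first
#' principal direction of the centered coordinates. The direction is
#' oriented from the first toward the last input point (its dot product
#' with `last - first` is non-negative), so reversing the input order flips
#' the sign.
#'
#' @param points n x 3 matrix of ordered coordinates (e.g. Cα atoms in
#'   residue order).
#' @return list of class `axis_fit` with `centroid`, unit `direction`, and
#'   `residual_rms` (Å, root mean square perpendicular distance).
#' @export
fit_axis <- function(points) {
  points <- rbind(points)
  if (nrow(points) < 3L) stop("axis fit requires at least 3 points")
  centroid <- colMeans(points)
  X <- sweep(points, 2L, centroid)
  if (max(abs(X)) < 1e-12) stop("axis fit of coincident points")
  s <- svd(X, nu = 0L, nv = 3L)
  dir <- s$v[, 1L]
  span <- points[nrow(points), ] - points[1L, ]
  if (sum(dir * span) < 0) dir <- -dir
  resid2 <- (sum(X^2) - s$d[1L]^2) / nrow(points)
  structure(list(centroid = centroid, direction = dir,
                 residual_rms = sqrt(max(resid2, 0))),
            class = "axis_fit")
}

#' Angle between two fitted axes
#'
#' Arc-cosine of the dot product of the oriented unit directions, in
#' degrees on `[0, 180]`. Orientation is preserved (an antiparallel helix
#' reads ~180°, not 0°).
#'
#' @param a,b `axis_fit` objects (or lists with a unit `direction`).
#' @return angle in degrees.
#' @export
axis_angle <- function(a, b) {
  d <- sum(a$direction * b$direction)
  acos(max(-1, min(1, d))) * 180 / pi
}

#' Per-frame distance between two atom selections
#'
#' Euclidean distance per frame between the mass-weighted centers of the
#' two selections (`mode = "com"`), or between single atoms
#' (`mode = "single"`, requiring one-atom selections).
#'
#' @param traj a [trajectory].
#' @param idxA,idxB integer atom index vectors, non-empty.
#' @param mode `"com"` or `"single"`.
#' @return numeric vector of distances (Å), one per frame.
#' @export
pair_distance_series <- function(traj, idxA, idxB, mode = c("com", "single")) {
  mode <- match.arg(mode)
  if (length(idxA) == 0L || length(idxB) == 0L) {
    stop("empty selection in pair_distance_series")
  }
  if (mode == "single" && (length(idxA) != 1L || length(idxB) != 1L)) {
    stop("mode 'single' requires one-atom selections")
  }
  mA <- traj$atoms$mass[idxA]
  mB <- traj$atoms$mass[idxB]
  vapply(seq_len(n_frames(traj)), function(k) {
    a <- center_of_mass(frame_coords(traj, k, idxA), mA)
    b <- center_of_mass(frame_coords(traj, k, idxB), mB)
    sqrt(sum((a - b)^2))
  }, numeric(1))
}
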