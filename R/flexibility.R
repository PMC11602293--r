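# Per-residue flexibility from coordinate trajectories: least-squares rigid
# superposition, RMSF at a given temperature, the high-minus-low RMSF
# difference used for candidate screening, and the auxiliary trajectory
# summaries (RMSD, radius of gyration, hydrogen-bond counts, SASA).

#' Least-squares rigid superposition (Kabsch)
#'
#' Superposes `mobile` onto `reference` with the optimal proper rotation and
#' translation, minimising the coordinate RMSD.
#'
#' @param mobile,reference Numeric `n x 3` coordinate matrices (Angstrom).
#' @param atom_mask Optional logical or integer index: atoms used to fit the
#'   transform (the whole `mobile` set is moved).
#' @return List with `aligned` (transformed mobile), `rmsd` (over the mask),
#'   `rotation` (3x3, det +1) and `translation`.
#' @export
kabsch_superpose <- function(mobile, reference, atom_mask = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  stopifnot(ncol(mobile) == 3L, ncol(reference) == 3L,
            nrow(mobile) == nrow(reference))
  mask <- atom_mask %||% seq_len(nrow(mobile))
  mm <- mobile[mask, , drop = FALSE]
  rr <- reference[mask, , drop = FALSE]
  if (nrow(mm) < 3L) {
    stop_msc("superposition needs >= 3 atoms in the mask, got %d", nrow(mm),
             class = "msc_degenerate_superposition_error")
  }
  cm <- colMeans(mm); cr <- colMeans(rr)
  a <- sweep(mm, 2, cm); b <- sweep(rr, 2, cr)
  # collinear sets leave the rotation about the common axis undetermined
  if (svd(a)$d[2] < 1e-8 * max(svd(a)$d[1], 1e-12)) {
    stop_msc("superposition atoms are (near-)collinear",
             class = "msc_degenerate_superposition_error")
  }
  s <- svd(crossprod(a, b))       # t(a) %*% b
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  aligned <- sweep(sweep(mobile, 2, cm) %*% t(rot), 2, cr, "+")
  dev <- aligned[mask, , drop = FALSE] - rr
  list(aligned = aligned,
       rmsd = sqrt(mean(rowSums(dev^2))),
       rotation = rot,
       translation = as.numeric(cr - cm %*% t(rot)))
}

#' Per-residue RMSF from a trajectory
#'
#' Root-mean-square fluctuation of each atom (one atom per residue, e.g.
#' C-alpha) about its time-mean position over the post-equilibration part of
#' the trajectory. The leading `equilibration_fraction` of frames is
#' discarded. With `superpose = TRUE` the retained frames are rigid-fitted in
#' two passes (align to the first retained frame, compute the mean structure,
#' realign every frame to that mean) before fluctuations are measured, so a
#' global rigid drift of the whole system does not inflate RMSF.
#'
#' @param traj `msc_trajectory`.
#' @param equilibration_fraction Fraction of leading frames discarded as
#'   equilibration, in `[0, 1)`. Default 0.5 (the first half of the run).
#' @param superpose Rigid-fit frames before measuring fluctuations.
#' @return Object of class `rmsf_profile`: list with `residue_ids`,
#'   `rmsf` (Angstrom), `temperature`, `equilibration_fraction`, `n_frames`.
#' @export
compute_rmsf <- function(traj, equilibration_fraction = 0.5, superpose = TRUE) {
  stopifnot(inherits(traj, "msc_trajectory"))
  if (equilibration_fraction < 0 || equilibration_fraction >= 1) {
    stop_msc("equilibration_fraction must be in [0, 1)", class = "msc_value_error")
  }
  nf <- dim(traj$coords)[1]
  keep <- seq.int(floor(nf * equilibration_fraction) + 1L, nf)
  if (length(keep) < 2L) {
    stop_msc("fewer than 2 post-equilibration frames (%d of %d retained)",
             length(keep), nf, class = "msc_insufficient_frames_error")
  }
  frames <- traj$coords[keep, , , drop = FALSE]
  if (superpose) {
    ref <- frames[1, , ]
    frames <- .align_all(frames, ref)
    mean1 <- apply(frames, c(2, 3), mean)
    frames <- .align_all(traj$coords[keep, , , drop = FALSE], mean1)
  }
  mean_xyz <- apply(frames, c(2, 3), mean)
  dev2 <- sweep(frames, c(2, 3), mean_xyz)^2
  sumsq <- matrix(dev2[, , 1] + dev2[, , 2] + dev2[, , 3],
                  nrow = dim(frames)[1])
  rmsf <- sqrt(colMeans(sumsq))
  structure(
    list(residue_ids = traj$residue_ids, rmsf = as.numeric(rmsf),
         temperature = traj$temperature,
         equilibration_fraction = equilibration_fraction,
         n_frames = length(keep)),
    class = "rmsf_profile"
  )
}

.align_all <- function(frames, ref) {
  for (f in seq_len(dim(frames)[1])) {
    frames[f, , ] <- kabsch_superpose(frames[f, , ], ref)$aligned
  }
  frames
}

#' RMSD time series against a reference frame
#'
#' @param traj `msc_trajectory`.
#' @param reference_frame Index of the reference frame (default 1).
#' @param superpose Rigid-fit each frame to the reference first.
#' @return Numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(traj, reference_frame = 1L, superpose = TRUE) {
  stopifnot(inherits(traj, "msc_trajectory"))
  ref <- traj$coords[reference_frame, , ]
  vapply(seq_len(dim(traj$coords)[1]), function(f) {
    fr <- traj$coords[f, , ]
    if (superpose) kabsch_superpose(fr, ref)$rmsd
    else sqrt(mean(rowSums((fr - ref)^2)))
  }, numeric(1))
}

#' High-minus-low RMSF difference per residue
#'
#' The screening statistic: RMSF at the high simulation temperature minus
#' RMSF at the low one, per residue. Large positive values mark residues
#' whose flexibility grows most on heating; negative values are possible.
#'
#' @param profile_high,profile_low `rmsf_profile` objects over identical
#'   residue id sets.
#' @return Object of class `flexibility_comparison`: data frame with columns
#'   `residue`, `rmsf_low`, `rmsf_high`, `delta` plus a `temperatures`
#'   attribute `c(low, high)`.
#' @export
delta_rmsf <- function(profile_high, profile_low) {
  ih <- profile_high$residue_ids; il <- profile_low$residue_ids
  extra_h <- setdiff(ih, il); extra_l <- setdiff(il, ih)
  if (length(extra_h) || length(extra_l)) {
    stop_msc("residue id mismatch; only-high: {%s}, only-low: {%s}",
             paste(extra_h, collapse = ","), paste(extra_l, collapse = ","),
             class = "msc_alignment_error")
  }
  ord <- match(ih, il)
  out <- data.frame(residue = ih,
                    rmsf_low = profile_low$rmsf[ord],
                    rmsf_high = profile_high$rmsf,
                    delta = profile_high$rmsf - profile_low$rmsf[ord])
  attr(out, "temperatures") <- c(low = profile_low$temperature,
                                 high = profile_high$temperature)
  class(out) <- c("flexibility_comparison", "data.frame")
  out
}

#' Flexibility comparison from a residue annotation table
#'
#' @param table `msc_residue_table`.
#' @param temperatures Length-2 numeric `c(low, high)` label, K.
#' @return `flexibility_comparison` computed from the two RMSF columns.
#' @export
comparison_from_table <- function(table, temperatures = c(298, 328)) {
  out <- data.frame(residue = table$residue,
                    rmsf_low = table$rmsf_low,
                    rmsf_high = table$rmsf_high,
                    delta = table$rmsf_high - table$rmsf_low)
  attr(out, "temperatures") <- c(low = temperatures[1], high = temperatures[2])
  class(out) <- c("flexibility_comparison", "data.frame")
  out
}

#' Radius of gyration of a coordinate frame
#'
#' Mass-weighted root-mean-square distance of the atoms from their centre
#' of mass.
#'
#' @param frame `n x 3` coordinate matrix (Angstrom).
#' @param masses Atomic masses (Da); default all 1.
#' @return Radius of gyration in Angstrom.
#' @export
radius_of_gyration <- function(frame, masses = NULL) {
  frame <- as.matrix(frame)
  if (is.null(dim(frame))) frame <- matrix(frame, ncol = 3)
  stopifnot(nrow(frame) >= 1L, ncol(frame) == 3L)
  masses <- masses %||% rep(1, nrow(frame))
  if (any(masses <= 0)) stop_msc("masses must be > 0", class = "msc_value_error")
  com <- colSums(frame * masses) / sum(masses)
  d2 <- rowSums(sweep(frame, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Count hydrogen bonds by a geometric criterion
#'
#' Counts donor-acceptor pairs with heavy-atom distance at most
#' `distance_cutoff`; when donor hydrogens are supplied the D-H...A angle at
#' the hydrogen must additionally be at least `angle_cutoff` degrees
#' (heavy-atom-only mode applies the distance criterion alone).
#'
#' @param donors `n x 3` donor heavy-atom coordinates.
#' @param acceptors `m x 3` acceptor coordinates.
#' @param hydrogens Optional `n x 3` coordinates of the hydrogen attached to
#'   each donor (row-aligned with `donors`).
#' @param distance_cutoff Donor-acceptor distance cutoff, Angstrom
#'   (default 3.5).
#' @param angle_cutoff Minimum D-H...A angle, degrees (default 120).
#' @return Integer count.
#' @export
count_hydrogen_bonds <- function(donors, acceptors, hydrogens = NULL,
                                 distance_cutoff = 3.5, angle_cutoff = 120) {
  donors <- .coerce_xyz(donors); acceptors <- .coerce_xyz(acceptors)
  if (nrow(donors) == 0L || nrow(acceptors) == 0L) return(0L)
  if (!is.null(hydrogens)) {
    hydrogens <- .coerce_xyz(hydrogens)
    stopifnot(nrow(hydrogens) == nrow(donors))
  }
  n <- 0L
  for (i in seq_len(nrow(donors))) {
    d2 <- rowSums(sweep(acceptors, 2, donors[i, ])^2)
    ok <- d2 <= distance_cutoff^2
    if (!is.null(hydrogens)) {
      h <- hydrogens[i, ]
      hd <- donors[i, ] - h
      for (j in which(ok)) {
        ha <- acceptors[j, ] - h
        cosang <- sum(hd * ha) / sqrt(sum(hd^2) * sum(ha^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang < angle_cutoff) ok[j] <- FALSE
      }
    }
    n <- n + sum(ok)
  }
  as.integer(n)
}

.coerce_xyz <- function(x) {
  x <- as.matrix(x)
  if (length(x) == 3L && is.null(dim(x))) x <- matrix(x, ncol = 3)
  if (ncol(x) != 3L) stop_msc("coordinates must be n x 3", class = "msc_value_error")
  x
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA: each atom's solvent-extended sphere (radius
#' `r_atom + probe_radius`) is sampled with a deterministic golden-spiral
#' point set; points falling inside any neighbouring extended sphere are
#' buried, and the exposed fraction times the sphere area is summed.
#'
#' @param frame `n x 3` atom coordinates (Angstrom).
#' @param radii Atomic radii, Angstrom (recycled; default 1.9).
#' @param probe_radius Solvent probe radius, Angstrom (default 1.4, water).
#' @param n_sphere_points Sample points per atom (default 960; minimum 32).
#' @return Total SASA in Angstrom^2, with per-atom values as attribute
#'   `per_atom`.
#' @export
shrake_rupley_sasa <- function(frame, radii = 1.9, probe_radius = 1.4,
                               n_sphere_points = 960) {
  frame <- .coerce_xyz(frame)
  n <- nrow(frame)
  radii <- rep_len(radii, n)
  if (any(radii <= 0) || probe_radius < 0) {
    stop_msc("radii must be > 0 and probe_radius >= 0", class = "msc_value_error")
  }
  if (n_sphere_points < 32) {
    stop_msc("n_sphere_points must be >= 32", class = "msc_value_error")
  }
  sphere <- .golden_spiral(n_sphere_points)
  ext <- radii + probe_radius
  per_atom <- numeric(n)
  for (i in seq_len(n)) {
    pts <- sweep(sphere * ext[i], 2, frame[i, ], "+")
    exposed <- rep(TRUE, n_sphere_points)
    for (j in seq_len(n)[-i]) {
      if (sum((frame[j, ] - frame[i, ])^2) > (ext[i] + ext[j])^2) next
      d2 <- rowSums(sweep(pts, 2, frame[j, ])^2)
      exposed <- exposed & d2 > ext[j]^2
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * ext[i]^2 * mean(exposed)
  }
  out <- sum(per_atom)
  attr(out, "per_atom") <- per_atom
  out
}

# Deterministic quasi-uniform unit-sphere point set (golden-angle spiral).
.golden_spiral <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' @export
print.rmsf_profile <- function(x, ...) {
  cat(sprintf("RMSF profile: %d residues, T = %s K, %d frames (equil. fraction %.2f)\n",
              length(x$residue_ids), format(x$temperature), x$n_frames,
              x$equilibration_fraction))
  cat(sprintf("  RMSF range %.3f - %.3f A\n", min(x$rmsf), max(x$rmsf)))
  invisible(x)
}
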