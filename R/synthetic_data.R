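# Ground-truth-controlled generators for every input the screen consumes:
# two-temperature jitter trajectories with prescribed per-residue
# fluctuation amplitudes, alignments with prescribed per-column
# conservation, pullable receptor-ligand systems with planted sticky
# residues, and noisy kinetic measurement series. All generators are pure
# functions of (spec, seed).

#' Specification for a synthetic two-temperature trajectory pair
#'
#' Residue `i` jitters isotropically about a fixed backbone position with
#' per-coordinate Gaussian standard deviation `sigma[i]` at the low
#' temperature and `sigma[i] * high_scale[i]` at the high one, so the
#' expected RMSF is `sigma * sqrt(3)` (low) and `sigma * high_scale *
#' sqrt(3)` (high).
#'
#' @param sigma Per-residue base positional sd, Angstrom (> 0).
#' @param high_scale Per-residue high-temperature scale factor (> 0,
#'   recycled).
#' @param n_frames Frames per trajectory (default 2000).
#' @param timestep Frame spacing, ps.
#' @param temp_low,temp_high Temperature labels, K (defaults 298 / 328).
#' @param residue_ids Residue ids (default `seq_along(sigma)`).
#' @return Object of class `flexibility_spec`.
#' @export
flexibility_spec <- function(sigma, high_scale = 1.5, n_frames = 2000,
                             timestep = 1, temp_low = 298, temp_high = 328,
                             residue_ids = NULL) {
  if (any(sigma <= 0)) stop_msc("sigma must be > 0", class = "msc_value_error")
  high_scale <- rep_len(high_scale, length(sigma))
  if (any(high_scale <= 0)) {
    stop_msc("high_scale must be > 0", class = "msc_value_error")
  }
  structure(
    list(sigma = sigma, high_scale = high_scale,
         n_frames = as.integer(n_frames), timestep = timestep,
         temp_low = temp_low, temp_high = temp_high,
         residue_ids = as.integer(residue_ids %||% seq_along(sigma))),
    class = "flexibility_spec"
  )
}

# Fixed helical backbone so superposition is well-conditioned.
.backbone <- function(n) {
  i <- seq_len(n)
  cbind(2.3 * cos(i * 100 * pi / 180),
        2.3 * sin(i * 100 * pi / 180),
        1.5 * i)
}

#' Generate a synthetic jitter trajectory
#'
#' @param spec `flexibility_spec`.
#' @param which `"low"` or `"high"` temperature member of the pair.
#' @param seed Integer seed (bit-identical output for a fixed seed).
#' @return `msc_trajectory`.
#' @export
gen_trajectory <- function(spec, which = c("low", "high"), seed = 1L) {
  stopifnot(inherits(spec, "flexibility_spec"))
  which <- match.arg(which)
  n <- length(spec$sigma)
  sd_i <- spec$sigma * if (which == "high") spec$high_scale else 1
  base <- .backbone(n)
  coords <- with_seed(seed, {
    arr <- array(stats::rnorm(spec$n_frames * n * 3), c(spec$n_frames, n, 3))
    arr <- sweep(arr, 2, sd_i, "*")
    sweep(arr, c(2, 3), base, "+")
  })
  msc_trajectory(coords, timestep = spec$timestep,
                 temperature = if (which == "high") spec$temp_high else spec$temp_low,
                 residue_ids = spec$residue_ids)
}

#' Generate an alignment with prescribed per-column conservation
#'
#' Each column is sampled independently: the modal residue with probability
#' `modal_freq`, any of the other 19 amino acids uniformly otherwise.
#' `modal_freq = 1` gives an invariant column (grade 9 downstream);
#' `modal_freq = 0.05` gives a uniform column (grade near 1 at depth).
#'
#' @param n_sequences Alignment depth (>= 2).
#' @param column_specs Data frame with columns `modal_residue` (single
#'   letters) and `modal_freq` (in `[1/20, 1]`).
#' @param seed Integer seed.
#' @return `msc_msa` with ids `seq001`, `seq002`, ...
#' @export
gen_msa <- function(n_sequences, column_specs, seed = 1L) {
  stopifnot(n_sequences >= 2L,
            all(c("modal_residue", "modal_freq") %in% names(column_specs)))
  p <- column_specs$modal_freq
  if (any(p < 1 / 20 - 1e-12 | p > 1)) {
    stop_msc("modal_freq must lie in [1/20, 1]", class = "msc_value_error")
  }
  modal <- toupper(column_specs$modal_residue)
  if (!all(modal %in% .AA20)) {
    stop_msc("modal_residue must be one of the 20 amino acids",
             class = "msc_value_error")
  }
  ncolumns <- nrow(column_specs)
  m <- with_seed(seed, {
    mm <- matrix("", n_sequences, ncolumns)
    for (j in seq_len(ncolumns)) {
      others <- setdiff(.AA20, modal[j])
      is_modal <- stats::runif(n_sequences) < p[j]
      mm[, j] <- ifelse(is_modal, modal[j],
                        others[sample.int(19L, n_sequences, replace = TRUE)])
    }
    mm
  })
  msc_msa(sprintf("seq%03d", seq_len(n_sequences)),
          apply(m, 1, paste, collapse = ""))
}

#' Generate a pullable receptor-ligand system with planted sticky residues
#'
#' The ligand (total mass 624.24 Da, apolar) sits at the origin with the
#' receptor shell behind it (negative x), so the pull proceeds along +x.
#' Planted "sticky" receptor residues are apolar atoms placed at the
#' Lennard-Jones minimum distance beside the start of the exit path with a
#' deep pair well, so they (a) trap the ligand until the controller has
#' escalated the acceleration and (b) stay within contact range for most of
#' the pull. All other receptor atoms are polar (never counted as
#' hydrophobic contacts) and placed clash-free away from the exit path.
#'
#' @param n_receptor Number of receptor atoms/residues (ids `1:n_receptor`).
#' @param n_ligand Ligand atoms (chain with harmonic bonds when > 1).
#' @param sticky_residues Receptor residue ids to plant as sticky (subset
#'   of `1:n_receptor`).
#' @param seed Integer seed.
#' @param ligand_mass Total ligand mass, Da (default 624.24).
#' @param pair_well_depth Sticky-pair Lennard-Jones well depth,
#'   Da Angstrom^2/ps^2 (default 40000; deep enough that escape requires
#'   several controller escalations at the default protocol).
#' @return `pull_system`.
#' @export
gen_pull_system <- function(n_receptor = 30, n_ligand = 1,
                            sticky_residues = integer(0), seed = 1L,
                            ligand_mass = 624.24, pair_well_depth = 40000) {
  sticky_residues <- as.integer(sticky_residues)
  if (length(setdiff(sticky_residues, seq_len(n_receptor)))) {
    stop_msc("sticky_residues must be a subset of 1..n_receptor",
             class = "msc_value_error")
  }
  eps_lig <- 200; sigma <- 3
  lig <- data.frame(
    x = 1.5 * (seq_len(n_ligand) - 1), y = 0, z = 0,
    mass = ligand_mass / n_ligand, apolar = TRUE,
    epsilon = eps_lig, sigma = sigma
  )
  bonds <- if (n_ligand > 1L) {
    data.frame(i = seq_len(n_ligand - 1L), j = seq_len(n_ligand - 1L) + 1L,
               r0 = 1.5, k = 10000)
  } else NULL

  rmin <- 2^(1 / 6) * sigma
  rec <- with_seed(seed, {
    pos <- matrix(NA_real_, n_receptor, 3)
    ns <- length(sticky_residues)
    if (ns) {
      # directly behind the first ligand atom on the pull axis, at the pair
      # LJ minimum, so the pull stretches the sticky pair radially and
      # escape requires the controller to escalate the acceleration
      for (k in seq_len(ns)) {
        z_off <- 1.2 * (k - 1)
        pos[sticky_residues[k], ] <- c(-sqrt(rmin^2 - z_off^2), 0, z_off)
      }
    }
    bulk <- setdiff(seq_len(n_receptor), sticky_residues)
    tries <- 0L
    for (idx in bulk) {
      repeat {
        tries <- tries + 1L
        if (tries > 10000L) {
          stop_msc("could not place receptor atoms clash-free after %d tries",
                   tries, class = "msc_generation_error")
        }
        cand <- c(stats::runif(1, -9, -4), stats::runif(1, -4, 4),
                  stats::runif(1, -4, 4))
        placed <- pos[!is.na(pos[, 1]), , drop = FALSE]
        ok_rec <- !nrow(placed) ||
          min(sqrt(rowSums(sweep(placed, 2, cand)^2))) >= 2
        ok_lig <- min(sqrt(rowSums(sweep(
          as.matrix(lig[, c("x", "y", "z")]), 2, cand)^2))) >= 4
        if (ok_rec && ok_lig) { pos[idx, ] <- cand; break }
      }
    }
    pos
  })
  receptor <- data.frame(
    residue_id = seq_len(n_receptor),
    x = rec[, 1], y = rec[, 2], z = rec[, 3],
    apolar = seq_len(n_receptor) %in% sticky_residues,
    # geometric-mean combination: receptor epsilon chosen so the sticky
    # pair well is pair_well_depth against the ligand's own epsilon
    epsilon = ifelse(seq_len(n_receptor) %in% sticky_residues,
                     pair_well_depth^2 / eps_lig, 50),
    sigma = sigma
  )
  build_system(receptor, lig, bonds)
}

#' Specification for synthetic kinetic measurement series
#'
#' @param Km True Michaelis constant (concentration units of
#'   `substrate_levels`).
#' @param kcat True turnover number, 1/s.
#' @param enzyme_conc Enzyme concentration (Vmax = kcat * enzyme_conc).
#' @param half_life True thermal-inactivation half-life, min.
#' @param noise_sd Multiplicative Gaussian noise sd (0 = noiseless).
#' @param substrate_levels Substrate design points; default 8 points
#'   geometric over 0.05 to 5 (the assay range, same unit as Km).
#' @param decay_times Incubation design points, min; default 10 to 100 by 10.
#' @param A0 Untreated activity, % (default 100).
#' @return Object of class `kinetics_spec`.
#' @export
kinetics_spec <- function(Km = 1.52, kcat = 7.10, enzyme_conc = 1,
                          half_life = 9.80, noise_sd = 0,
                          substrate_levels = NULL, decay_times = NULL,
                          A0 = 100) {
  if (Km <= 0 || kcat <= 0 || enzyme_conc <= 0 || half_life <= 0 || A0 <= 0) {
    stop_msc("kinetic parameters must be > 0", class = "msc_value_error")
  }
  if (noise_sd < 0) stop_msc("noise_sd must be >= 0", class = "msc_value_error")
  structure(
    list(Km = Km, kcat = kcat, enzyme_conc = enzyme_conc,
         half_life = half_life, noise_sd = noise_sd,
         substrate_levels = substrate_levels %||%
           exp(seq(log(0.05), log(5), length.out = 8)),
         decay_times = decay_times %||% seq(10, 100, by = 10),
         A0 = A0),
    class = "kinetics_spec"
  )
}

#' Preset kinetics spec for a published variant
#'
#' @param variant One of `"rAprY"`, `"A216E"`, `"A216K"`, `"A216R"`.
#' @param ... Overrides passed to [kinetics_spec()] (e.g. `noise_sd`).
#' @return `kinetics_spec` with the variant's Km, kcat and half-life.
#' @export
kinetics_spec_preset <- function(variant = "rAprY", ...) {
  presets <- kinetics_presets()
  row <- presets[presets$variant == variant, ]
  if (nrow(row) != 1L) {
    stop_msc("unknown variant '%s' (known: %s)", variant,
             paste(presets$variant, collapse = ", "), class = "msc_value_error")
  }
  kinetics_spec(Km = row$Km, kcat = row$kcat, half_life = row$half_life, ...)
}

#' Generate noisy kinetic measurement series
#'
#' Michaelis-Menten initial rates at the design substrate levels and
#' residual activities at the design incubation times, with multiplicative
#' Gaussian noise (`y * (1 + eps)`, `eps ~ N(0, noise_sd)`); noiseless when
#' `noise_sd = 0`.
#'
#' @param spec `kinetics_spec`.
#' @param seed Integer seed.
#' @return List with `mm` (data frame `substrate`, `rate`) and `decay`
#'   (data frame `time`, `activity`), plus the `spec`.
#' @export
gen_kinetic_series <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "kinetics_spec"))
  vmax <- spec$kcat * spec$enzyme_conc
  s <- spec$substrate_levels
  v_true <- vmax * s / (spec$Km + s)
  a_true <- spec$A0 * 2^(-spec$decay_times / spec$half_life)
  noisy <- with_seed(seed, {
    list(v = v_true * (1 + stats::rnorm(length(v_true), sd = spec$noise_sd)),
         a = a_true * (1 + stats::rnorm(length(a_true), sd = spec$noise_sd)))
  })
  list(mm = data.frame(substrate = s, rate = pmax(noisy$v, 1e-9)),
       decay = data.frame(time = spec$decay_times,
                          activity = pmax(noisy$a, 1e-9)),
       spec = spec)
}
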