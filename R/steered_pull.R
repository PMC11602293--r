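# Desk-scale steered-pulling simulator. A rigid receptor and a mobile ligand
# (12-6 Lennard-Jones nonbonded forces, harmonic intra-ligand bonds) are
# integrated with velocity Verlet while an external acceleration pulls every
# ligand atom along the continuously updated receptor-to-ligand
# centre-of-mass direction. The acceleration is adaptive:
#   * it starts at a floor of 2000 pm/ps^2,
#   * if the maximum receptor-ligand COM separation has not increased for
#     400 steps it grows by 500 pm/ps^2,
#   * every 20 steps, if the maximum separation grows faster than 4000 m/s
#     the acceleration is scaled by 1 - (1 - 4000/MaxDisSpeed)^2, never
#     below the floor.
# The run ends once the ligand COM has moved 15 Angstrom from its start.
# Forces are reported in pN through F = m * a * 0.00166 with m in Da and a
# in pm/ps^2. Internal units: Angstrom, ps, Da (accelerations converted
# from pm/ps^2 with a factor 0.01).

#' Steered-pull protocol parameters
#'
#' Bundles the adaptive-acceleration controller constants and run controls.
#' Defaults are the published protocol: acceleration floor 2000 pm/ps^2,
#' +500 pm/ps^2 after 400 stagnant steps, speed cap 4000 m/s checked every
#' 20 steps, 15 Angstrom stop displacement, 3 ps equilibration, and the
#' 0.00166 pN per (Da pm/ps^2) force conversion.
#'
#' @param a_min Acceleration floor, pm/ps^2.
#' @param a_increment Stagnation increment, pm/ps^2 (must be <= `a_min`).
#' @param stagnation_window Steps without a new maximum separation before
#'   the increment fires.
#' @param speed_cap Maximum-separation growth-rate cap, m/s.
#' @param scale_check_interval Steps between speed checks.
#' @param stop_displacement Ligand COM displacement ending the run, Angstrom.
#' @param equilibration_time Unforced equilibration before pulling, ps.
#' @param timestep_fs Integration timestep, fs.
#' @param force_conversion pN per (Da pm/ps^2).
#' @param contact_cutoff Apolar-apolar contact distance, Angstrom.
#' @param max_steps Hard cap on pulling steps (non-termination guard).
#' @return Object of class `pull_protocol` (a validated list).
#' @export
pull_protocol <- function(a_min = 2000, a_increment = 500,
                          stagnation_window = 400, speed_cap = 4000,
                          scale_check_interval = 20, stop_displacement = 15,
                          equilibration_time = 3, timestep_fs = 1.25,
                          force_conversion = 0.00166,
                          contact_cutoff = 5, max_steps = 200000L) {
  p <- list(a_min = a_min, a_increment = a_increment,
            stagnation_window = stagnation_window, speed_cap = speed_cap,
            scale_check_interval = scale_check_interval,
            stop_displacement = stop_displacement,
            equilibration_time = equilibration_time,
            timestep_fs = timestep_fs, force_conversion = force_conversion,
            contact_cutoff = contact_cutoff, max_steps = as.integer(max_steps))
  pos <- c("a_min", "a_increment", "stagnation_window", "speed_cap",
           "scale_check_interval", "stop_displacement", "timestep_fs",
           "force_conversion", "contact_cutoff", "max_steps")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || p[[f]] <= 0) {
      stop_msc("protocol field '%s' must be a positive scalar", f,
               class = "msc_value_error")
    }
  }
  if (p$equilibration_time < 0) {
    stop_msc("equilibration_time must be >= 0", class = "msc_value_error")
  }
  if (p$a_increment > p$a_min) {
    stop_msc("a_increment (%g) must not exceed a_min (%g)",
             p$a_increment, p$a_min, class = "msc_value_error")
  }
  structure(p, class = "pull_protocol")
}

#' Build a receptor-ligand pulling system
#'
#' The receptor is held fixed; the ligand moves. Atoms carry an
#' apolar/polar class from which Lennard-Jones parameters are assigned
#' deterministically (per-atom `epsilon`/`sigma` columns override the class
#' defaults). Any atom pair closer than half its combined LJ sigma is a
#' steric clash and rejects the system.
#'
#' @param receptor Data frame with columns `residue_id`, `x`, `y`, `z`,
#'   `apolar` (logical), optional `epsilon`, `sigma`. May be `NULL` or empty
#'   (free ligand; the pull direction is then fixed).
#' @param ligand Data frame with columns `x`, `y`, `z`, `mass` (Da),
#'   `apolar`, optional `epsilon`, `sigma`.
#' @param bonds Optional intra-ligand harmonic bonds: data frame `i`, `j`,
#'   `r0` (Angstrom), `k` (Da/ps^2).
#' @param params List of class defaults: `epsilon_apolar`, `epsilon_polar`
#'   (Da Angstrom^2/ps^2), `sigma` (Angstrom), `nonbonded_cutoff` (Angstrom).
#' @return Object of class `pull_system`.
#' @export
build_system <- function(receptor = NULL, ligand, bonds = NULL,
                         params = list()) {
  defaults <- list(epsilon_apolar = 200, epsilon_polar = 50, sigma = 3,
                   nonbonded_cutoff = 10)
  params <- utils::modifyList(defaults, params)
  if (params$nonbonded_cutoff <= 0) {
    stop_msc("nonbonded_cutoff must be > 0", class = "msc_value_error")
  }
  ligand <- as.data.frame(ligand)
  stopifnot(all(c("x", "y", "z", "mass", "apolar") %in% names(ligand)),
            nrow(ligand) >= 1L)
  if (sum(ligand$mass) <= 0 || any(ligand$mass <= 0)) {
    stop_msc("ligand masses must be > 0", class = "msc_value_error")
  }
  assign_lj <- function(df) {
    if (is.null(df$epsilon)) {
      df$epsilon <- ifelse(df$apolar, params$epsilon_apolar, params$epsilon_polar)
    }
    if (is.null(df$sigma)) df$sigma <- params$sigma
    df
  }
  ligand <- assign_lj(ligand)
  if (!is.null(receptor) && nrow(as.data.frame(receptor)) > 0L) {
    receptor <- assign_lj(as.data.frame(receptor))
    stopifnot(all(c("residue_id", "x", "y", "z", "apolar") %in% names(receptor)))
  } else {
    receptor <- NULL
  }
  sys <- structure(
    list(receptor = receptor, ligand = ligand,
         bonds = if (!is.null(bonds) && nrow(as.data.frame(bonds)) > 0L)
           as.data.frame(bonds) else NULL,
         nonbonded_cutoff = params$nonbonded_cutoff),
    class = "pull_system"
  )
  clashes <- .find_clashes(sys)
  if (nrow(clashes)) {
    stop_msc("steric clash in built system: %s",
             paste(sprintf("(%s-%s @ %.2f A)", clashes$a, clashes$b, clashes$d),
                   collapse = ", "),
             class = "msc_clash_error")
  }
  sys
}

.find_clashes <- function(sys) {
  out <- data.frame(a = character(), b = character(), d = numeric())
  lig <- as.matrix(sys$ligand[, c("x", "y", "z")])
  if (!is.null(sys$receptor)) {
    rec <- as.matrix(sys$receptor[, c("x", "y", "z")])
    for (i in seq_len(nrow(lig))) {
      d <- sqrt(rowSums(sweep(rec, 2, lig[i, ])^2))
      sij <- (sys$receptor$sigma + sys$ligand$sigma[i]) / 2
      bad <- which(d < 0.5 * sij)
      if (length(bad)) {
        out <- rbind(out, data.frame(
          a = sprintf("lig%d", i),
          b = sprintf("rec%d", sys$receptor$residue_id[bad]),
          d = d[bad]))
      }
    }
  }
  if (nrow(lig) > 1L) {
    bonded <- if (!is.null(sys$bonds))
      paste(pmin(sys$bonds$i, sys$bonds$j), pmax(sys$bonds$i, sys$bonds$j))
    else character(0)
    for (i in seq_len(nrow(lig) - 1L)) {
      for (j in seq.int(i + 1L, nrow(lig))) {
        if (paste(i, j) %in% bonded) next
        d <- sqrt(sum((lig[i, ] - lig[j, ])^2))
        sij <- (sys$ligand$sigma[i] + sys$ligand$sigma[j]) / 2
        if (d < 0.5 * sij) {
          out <- rbind(out, data.frame(a = sprintf("lig%d", i),
                                       b = sprintf("lig%d", j), d = d))
        }
      }
    }
  }
  out
}

#' One step of the adaptive acceleration controller
#'
#' Pure controller rule, exposed for unit-level use: if the maximum
#' receptor-ligand COM separation has not increased for at least
#' `stagnation_window` steps, add `a_increment`; otherwise, on a
#' scale-check step whose measured `max_dis_speed` exceeds `speed_cap`,
#' multiply by `1 - (1 - speed_cap / max_dis_speed)^2`. The result is never
#' below `a_min`.
#'
#' @param state List with `current_acceleration` (pm/ps^2),
#'   `steps_since_max_increase`, `step_index`, and `max_dis_speed` (m/s;
#'   `NA` when not measured this step).
#' @param protocol `pull_protocol`.
#' @return New acceleration, pm/ps^2.
#' @export
update_acceleration <- function(state, protocol) {
  a <- state$current_acceleration
  if (state$steps_since_max_increase >= protocol$stagnation_window) {
    a <- a + protocol$a_increment
  } else if (state$step_index %% protocol$scale_check_interval == 0 &&
             !is.na(state$max_dis_speed) &&
             state$max_dis_speed > protocol$speed_cap) {
    a <- a * (1 - (1 - protocol$speed_cap / state$max_dis_speed)^2)
  }
  max(a, protocol$a_min)
}

#' Pulling force from mass and acceleration
#'
#' `F = m * a * conversion`, in pN, with mass in Da and acceleration in
#' pm/ps^2.
#'
#' @param mass Mass, Da (> 0).
#' @param acceleration Acceleration, pm/ps^2.
#' @param conversion pN per (Da pm/ps^2); default 0.00166.
#' @return Force in pN.
#' @export
force_from_acceleration <- function(mass, acceleration, conversion = 0.00166) {
  if (any(mass <= 0)) stop_msc("mass must be > 0", class = "msc_value_error")
  mass * acceleration * conversion
}

#' Run a steered pull
#'
#' Velocity-Verlet integration of the ligand under receptor Lennard-Jones
#' forces, intra-ligand harmonic bonds, and the adaptive external pulling
#' acceleration applied to every ligand atom along the continuously updated
#' receptor-to-ligand COM direction. After an unforced equilibration period
#' the pull starts; the run terminates once the ligand COM has moved
#' `stop_displacement` from its starting point.
#'
#' @param system `pull_system`.
#' @param protocol `pull_protocol`.
#' @param seed Integer seed for the Maxwell-Boltzmann initial velocities.
#' @param init_temperature Initial-velocity temperature, K. `0` gives a
#'   deterministic run from rest (used for closed-form checks).
#' @return Object of class `pull_result`: list with `peak_force` (pN),
#'   `total_work` (pN Angstrom), `displacement_series` (Angstrom per step),
#'   `acceleration_series` (pm/ps^2), `force_series` (pN),
#'   `contact_timeline` (per-step integer vectors of receptor residues in
#'   apolar contact), `contact_counts`, `n_steps`, `time_ps`, `protocol`.
#' @export
run_pull <- function(system, protocol = pull_protocol(), seed = 1L,
                     init_temperature = 298) {
  stopifnot(inherits(system, "pull_system"), inherits(protocol, "pull_protocol"))
  dt <- protocol$timestep_fs * 1e-3           # ps
  lig <- system$ligand
  x <- as.matrix(lig[, c("x", "y", "z")])
  m <- lig$mass
  mtot <- sum(m)
  has_rec <- !is.null(system$receptor)
  rec <- if (has_rec) as.matrix(system$receptor[, c("x", "y", "z")]) else NULL
  rec_com <- if (has_rec) colSums(rec * 1) / nrow(rec) else NULL
  apolar_rec <- if (has_rec) which(system$receptor$apolar) else integer(0)
  apolar_lig <- which(lig$apolar)
  cutoff2 <- system$nonbonded_cutoff^2
  contact2 <- protocol$contact_cutoff^2

  v <- matrix(0, nrow(x), 3)
  if (init_temperature > 0) {
    v <- with_seed(seed, {
      matrix(stats::rnorm(3 * nrow(x)), nrow(x), 3) *
        sqrt(.kB * init_temperature / m)
    })
  }

  lj_eps <- if (has_rec)
    sqrt(outer(lig$epsilon, system$receptor$epsilon)) else NULL
  lj_sig <- if (has_rec)
    outer(lig$sigma, system$receptor$sigma, function(a, b) (a + b) / 2) else NULL

  internal_force <- function(x) {
    f <- matrix(0, nrow(x), 3)
    if (has_rec) {
      for (i in seq_len(nrow(x))) {
        dvec <- sweep(rec, 2, x[i, ], "-")       # ligand -> receptor
        r2 <- rowSums(dvec^2)
        sel <- which(r2 <= cutoff2)
        if (!length(sel)) next
        r2s <- r2[sel]
        sr2 <- lj_sig[i, sel]^2 / r2s
        sr6 <- sr2^3
        # dU/dr * (1/r); positive coefficient pushes the ligand atom away
        coef <- 24 * lj_eps[i, sel] * (2 * sr6^2 - sr6) / r2s
        f[i, ] <- f[i, ] - colSums(dvec[sel, , drop = FALSE] * coef)
      }
    }
    if (!is.null(system$bonds)) {
      for (b in seq_len(nrow(system$bonds))) {
        i <- system$bonds$i[b]; j <- system$bonds$j[b]
        dvec <- x[j, ] - x[i, ]
        r <- sqrt(sum(dvec^2))
        if (r < 1e-12) next
        fb <- system$bonds$k[b] * (r - system$bonds$r0[b]) * dvec / r
        f[i, ] <- f[i, ] + fb
        f[j, ] <- f[j, ] - fb
      }
    }
    f
  }

  com <- function(x) colSums(x * m) / mtot
  start_com <- com(x)
  fixed_dir <- c(1, 0, 0)
  pull_dir <- function(x) {
    if (!has_rec) return(fixed_dir)
    d <- com(x) - rec_com
    n <- sqrt(sum(d^2))
    if (n < 1e-9) fixed_dir else d / n
  }
  com_sep <- function(x) {
    if (has_rec) sqrt(sum((com(x) - rec_com)^2))
    else sqrt(sum((com(x) - start_com)^2))
  }

  # unforced equilibration
  n_eq <- round(protocol$equilibration_time / dt)
  f <- internal_force(x)
  if (n_eq > 0) {
    for (s in seq_len(n_eq)) {
      x <- x + v * dt + 0.5 * (f / m) * dt^2
      fn <- internal_force(x)
      v <- v + 0.5 * ((f + fn) / m) * dt
      f <- fn
    }
  }

  # pulling phase
  start_com <- com(x)
  a_cur <- protocol$a_min
  max_sep <- com_sep(x)
  max_sep_last_check <- max_sep
  steps_since <- 0L
  n_alloc <- 4096L
  disp_series <- accel_series <- force_series <- numeric(n_alloc)
  contact_timeline <- vector("list", n_alloc)
  contact_counts <- integer(0)
  work <- 0
  proj_prev <- 0
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > protocol$max_steps) {
      stop_msc(paste0("pull did not terminate within %d steps ",
                      "(displacement %.2f of %.2f A, acceleration %g pm/ps^2)"),
               protocol$max_steps, sqrt(sum((com(x) - start_com)^2)),
               protocol$stop_displacement, a_cur,
               class = "msc_nontermination_error")
    }
    if (step > n_alloc) {
      n_alloc <- n_alloc * 2L
      length(disp_series) <- length(accel_series) <- length(force_series) <- n_alloc
      length(contact_timeline) <- n_alloc
    }
    u <- pull_dir(x)
    a_ext <- a_cur * .PM_PER_A                  # A/ps^2
    fe <- outer(m * a_ext, u)                   # external force per atom
    ft <- f + fe
    x <- x + v * dt + 0.5 * (ft / m) * dt^2
    fn <- internal_force(x)
    ftn <- fn + outer(m * a_ext, pull_dir(x))
    v <- v + 0.5 * ((ft + ftn) / m) * dt
    f <- fn

    cur_com <- com(x)
    sep <- com_sep(x)
    if (sep > max_sep) {
      max_sep <- sep
      steps_since <- 0L
    } else {
      steps_since <- steps_since + 1L
    }
    speed <- NA_real_
    if (step %% protocol$scale_check_interval == 0L) {
      # growth rate of the maximum separation over the check interval,
      # converted A/ps -> m/s (x100)
      speed <- (max_sep - max_sep_last_check) /
        (protocol$scale_check_interval * dt) * 100
      max_sep_last_check <- max_sep
    }

    force_pN <- force_from_acceleration(mtot, a_cur, protocol$force_conversion)
    disp_vec <- cur_com - start_com
    proj <- sum(disp_vec * u)
    work <- work + force_pN * (proj - proj_prev)
    proj_prev <- proj

    disp <- sqrt(sum(disp_vec^2))
    disp_series[step] <- disp
    accel_series[step] <- a_cur
    force_series[step] <- force_pN
    if (length(apolar_rec) && length(apolar_lig)) {
      hit <- apolar_rec[vapply(apolar_rec, function(j) {
        any(rowSums(sweep(x[apolar_lig, , drop = FALSE], 2, rec[j, ])^2) <= contact2)
      }, logical(1))]
      contact_timeline[[step]] <- as.integer(system$receptor$residue_id[hit])
    } else {
      contact_timeline[[step]] <- integer(0)
    }

    if (disp >= protocol$stop_displacement) break

    new_a <- update_acceleration(
      list(current_acceleration = a_cur, steps_since_max_increase = steps_since,
           step_index = step, max_dis_speed = speed), protocol)
    if (new_a > a_cur && steps_since >= protocol$stagnation_window) {
      steps_since <- 0L
    }
    a_cur <- new_a
  }

  contact_timeline <- contact_timeline[seq_len(step)]
  all_ids <- unlist(contact_timeline)
  counts <- if (length(all_ids)) table(all_ids) else table(integer(0))
  structure(
    list(peak_force = max(force_series[seq_len(step)]),
         total_work = work,
         displacement_series = disp_series[seq_len(step)],
         acceleration_series = accel_series[seq_len(step)],
         force_series = force_series[seq_len(step)],
         contact_timeline = contact_timeline,
         contact_counts = counts,
         n_steps = step,
         time_ps = step * dt,
         protocol = protocol),
    class = "pull_result"
  )
}

#' Receptor residues with prolonged substrate contact
#'
#' Residues whose apolar-apolar contact with any ligand atom (at the
#' protocol's contact cutoff, recorded during the run) persists for at
#' least `persistence_fraction` of the pulling steps.
#'
#' @param result `pull_result`.
#' @param persistence_fraction Fraction of pull steps a contact must
#'   persist (default 0.5).
#' @return Sorted integer vector of receptor residue ids (possibly empty).
#' @export
prolonged_contacts <- function(result, persistence_fraction = 0.5) {
  stopifnot(inherits(result, "pull_result"))
  if (result$n_steps == 0L || length(result$contact_counts) == 0L) {
    return(integer(0))
  }
  frac <- as.numeric(result$contact_counts) / result$n_steps
  sort(as.integer(names(result$contact_counts)[frac >= persistence_fraction]))
}

#' @export
print.pull_result <- function(x, ...) {
  cat(sprintf("Steered pull: %d steps (%.3f ps), peak force %.1f pN, work %.0f pN*A\n",
              x$n_steps, x$time_ps, x$peak_force, x$total_work))
  pc <- prolonged_contacts(x)
  cat(sprintf("  prolonged contacts (>=50%% of steps): %s\n",
              if (length(pc)) paste(pc, collapse = ", ") else "none"))
  invisible(x)
}
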