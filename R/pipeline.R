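# End-to-end orchestration of the three-stage screen from a configuration
# list (or YAML file): flexibility comparison -> substrate contacts ->
# conservation grades -> selection, with a reproducible report. Each stage
# accepts either raw inputs (trajectory pair, pull system, alignment) or a
# precomputed annotation table, because published per-residue tables are
# printable and re-runnable while the underlying all-atom trajectories are
# not.

#' Build a screen configuration
#'
#' @param rmsf List describing the flexibility source: either
#'   `list(table = path)` (use the `rmsf_low`/`rmsf_high` columns of a
#'   residue annotation table) or `list(trajectory_low = path,
#'   trajectory_high = path, equilibration_fraction = 0.5)`.
#' @param contacts Contact source: `list(source = "table", table = path)`
#'   (flag column), `list(source = "residues", residues = c(...))`, or
#'   `list(source = "pull", system = <pull_system>, protocol = ...,
#'   persistence_fraction = 0.5)`.
#' @param grades Grade source: `list(source = "table", table = path)` or
#'   `list(source = "msa", msa = path, reference_id = ..., structure_ids =
#'   ...)`.
#' @param threshold Stage-1 threshold, Angstrom (default 0.05).
#' @param excluded_grade Strictly conserved grade (default 9).
#' @param missing_grade Policy for missing grades, `"keep"` or `"drop"`.
#' @param seed Integer seed for any stochastic stage.
#' @param output_dir Optional directory for the report files.
#' @return Configuration list of class `screen_config`.
#' @export
screen_config <- function(rmsf, contacts = NULL, grades = NULL,
                          threshold = 0.05, excluded_grade = 9L,
                          missing_grade = "keep", seed = 1L,
                          output_dir = NULL) {
  if (threshold < 0) stop_msc("threshold must be >= 0", class = "msc_value_error")
  # single-table shorthand: contacts and grades default to the same table
  if (!is.null(rmsf$table)) {
    contacts <- contacts %||% list(source = "table", table = rmsf$table)
    grades <- grades %||% list(source = "table", table = rmsf$table)
  }
  if (is.null(contacts) || is.null(grades)) {
    stop_msc("contacts and grades sources must be configured",
             class = "msc_value_error")
  }
  structure(
    list(rmsf = rmsf, contacts = contacts, grades = grades,
         threshold = threshold, excluded_grade = as.integer(excluded_grade),
         missing_grade = missing_grade, seed = as.integer(seed),
         output_dir = output_dir),
    class = "screen_config"
  )
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_msc("screen stage '%s' failed: %s", name, conditionMessage(e),
             class = "msc_stage_error")
  })
}

#' Run the full candidate-site screen
#'
#' Executes the stages in order (flexibility comparison, substrate
#' contacts, conservation grades, three-stage selection), writes a report
#' (`report.json`, per-stage TSVs and a parameter log) when an output
#' directory is configured, and returns the selection report. Output files
#' contain no timestamps, so a rerun with the same configuration and seed
#' reproduces them byte-identically.
#'
#' @param config `screen_config`, a plain list with the same shape, or the
#'   path of a YAML file encoding one.
#' @return List of class `screen_result`: `report` (`selection_report`),
#'   `comparison`, `contacts`, `grades`, `log` (character lines), `files`
#'   (paths written, or `NULL`).
#' @export
run_screen <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!inherits(config, "screen_config")) {
    config <- do.call(screen_config, config)
  }
  log <- c(sprintf("threshold_A: %g", config$threshold),
           sprintf("excluded_grade: %d", config$excluded_grade),
           sprintf("missing_grade_policy: %s", config$missing_grade),
           sprintf("seed: %d", config$seed))

  comparison <- .stage("flexibility", {
    r <- config$rmsf
    if (!is.null(r$table)) {
      log <- c(log, sprintf("rmsf_source: table %s", r$table))
      comparison_from_table(read_residue_table(r$table))
    } else {
      ef <- r$equilibration_fraction %||% 0.5
      lo <- read_trajectory(r$trajectory_low, temperature = r$temp_low %||% 298)
      hi <- read_trajectory(r$trajectory_high, temperature = r$temp_high %||% 328)
      log <- c(log, sprintf("rmsf_source: trajectories %s / %s (equil %g)",
                            r$trajectory_low, r$trajectory_high, ef))
      delta_rmsf(compute_rmsf(hi, ef), compute_rmsf(lo, ef))
    }
  })

  contacts <- .stage("contacts", {
    cc <- config$contacts
    switch(cc$source %||% "table",
      table = {
        tab <- read_residue_table(cc$table)
        log <- c(log, sprintf("contacts_source: table %s", cc$table))
        tab$residue[tab$contact]
      },
      residues = {
        log <- c(log, "contacts_source: explicit residue list")
        as.integer(cc$residues)
      },
      pull = {
        pr <- run_pull(cc$system, cc$protocol %||% pull_protocol(),
                       seed = config$seed)
        pf <- cc$persistence_fraction %||% 0.5
        log <- c(log, sprintf("contacts_source: steered pull (%d steps, persistence %g)",
                              pr$n_steps, pf))
        prolonged_contacts(pr, pf)
      },
      stop_msc("unknown contacts source '%s'", cc$source, class = "msc_value_error")
    )
  })

  grades <- .stage("conservation", {
    gg <- config$grades
    switch(gg$source %||% "table",
      table = {
        tab <- read_residue_table(gg$table)
        log <- c(log, sprintf("grades_source: table %s", gg$table))
        data.frame(residue = tab$residue, grade = tab$conservation)
      },
      msa = {
        msa <- if (inherits(gg$msa, "msc_msa")) gg$msa else read_msa(gg$msa)
        prof <- conservation_profile(msa, gg$reference_id, gg$structure_ids)
        log <- c(log, sprintf("grades_source: alignment (%d rows)", length(msa$ids)))
        data.frame(residue = prof$residue, grade = prof$grade)
      },
      stop_msc("unknown grades source '%s'", gg$source, class = "msc_value_error")
    )
  })

  report <- .stage("selection", {
    select_candidates(comparison, contacts, grades,
                      threshold = config$threshold,
                      excluded_grade = config$excluded_grade,
                      missing_grade = config$missing_grade)
  })

  log <- c(log,
           sprintf("stage1_pass: %d of %d input residues",
                   length(report$stage1_pass), length(report$input_residues)),
           sprintf("stage2_removed: %d", length(report$stage2_removed)),
           sprintf("stage3_removed: %d", length(report$stage3_removed)),
           sprintf("bookkeeping: %d - %d - %d = %d final candidates",
                   length(report$stage1_pass), length(report$stage2_removed),
                   length(report$stage3_removed), length(report$final_candidates)),
           vapply(report$notes, function(n) paste("note:", n), character(1)))
  # flag residues admitted right at the margin of the strict threshold,
  # where a printed table rounded to 3 decimals can disagree with prose
  margin <- comparison$residue[comparison$delta > config$threshold &
                                 comparison$delta <= config$threshold + 0.05]
  if (length(margin)) {
    log <- c(log, sprintf("flag: residues within 0.05 A above the threshold (literal rule applied): %s",
                          paste(margin, collapse = ", ")))
  }

  files <- NULL
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    jsonlite::write_json(
      list(parameters = report$parameters,
           input_residues = report$input_residues,
           stage1_pass = report$stage1_pass,
           stage2_removed = report$stage2_removed,
           stage3_removed = report$stage3_removed,
           final_candidates = report$final_candidates,
           notes = report$notes),
      out("report.json"), auto_unbox = FALSE, digits = NA, pretty = TRUE)
    utils::write.table(as.data.frame(comparison), out("stage1_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(report$removals, out("removals.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(log, out("screen.log"))
    files <- c(out("report.json"), out("stage1_comparison.tsv"),
               out("removals.tsv"), out("screen.log"))
  }

  structure(list(report = report, comparison = comparison, contacts = contacts,
                 grades = grades, log = log, files = files),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  print(x$report)
  invisible(x)
}
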