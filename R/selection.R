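# The three-stage candidate selection at the heart of the screen:
#   stage 1  keep residues whose high-minus-low RMSF difference exceeds a
#            threshold (default 0.05 Angstrom, strict inequality);
#   stage 2  remove residues with prolonged hydrophobic substrate contacts
#            seen during steered pulling;
#   stage 3  remove strictly conserved residues (grade 9 by default).
# Every removal is recorded with its reason so the report accounts for each
# input residue exactly once.

#' Stage-1 flexibility filter
#'
#' Residues whose RMSF difference (high temperature minus low) is strictly
#' greater than the threshold.
#'
#' @param comparison `flexibility_comparison` (or data frame with columns
#'   `residue`, `delta`).
#' @param threshold Threshold in Angstrom (default 0.05).
#' @return Integer vector of residue ids.
#' @export
flexibility_filter <- function(comparison, threshold = 0.05) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  as.integer(comparison$residue[comparison$delta > threshold])
}

#' Three-stage candidate selection
#'
#' Applies the flexibility threshold, then subtracts substrate-contact
#' residues, then excludes strictly conserved residues. Contact residues
#' that did not survive stage 1 are logged as notes, not errors. Residues
#' with a missing conservation grade are kept by default (exclusion requires
#' positive evidence of strict conservation) or dropped when
#' `missing_grade = "drop"`.
#'
#' @param comparison `flexibility_comparison` (columns `residue`, `delta`).
#' @param contacts Integer vector of substrate-contact residue ids.
#' @param grades Named integer vector (names = residue ids) or data frame
#'   with columns `residue` and `grade` (a `conservation` column is also
#'   accepted). Grades in 1..9, NA = unknown.
#' @param threshold Stage-1 threshold, Angstrom (default 0.05).
#' @param excluded_grade Grade treated as strictly conserved (default 9).
#' @param missing_grade `"keep"` (default) or `"drop"`.
#' @return Object of class `selection_report`: list with `input_residues`,
#'   `stage1_pass`, `stage2_removed`, `stage3_removed`, `final_candidates`,
#'   `removals` (data frame residue/stage/reason), `notes`, `parameters`.
#' @export
select_candidates <- function(comparison, contacts, grades,
                              threshold = 0.05, excluded_grade = 9L,
                              missing_grade = c("keep", "drop")) {
  missing_grade <- match.arg(missing_grade)
  input <- as.integer(comparison$residue)
  contacts <- as.integer(contacts)
  grade_map <- .grade_lookup(grades)

  stage1 <- flexibility_filter(comparison, threshold)
  notes <- character(0)

  stage2_removed <- intersect(stage1, contacts)
  outside <- setdiff(contacts, stage1)
  if (length(outside)) {
    notes <- c(notes, sprintf(
      "contact residue(s) %s not in the stage-1 set; logged, nothing to remove",
      paste(outside, collapse = ", ")))
  }
  after2 <- setdiff(stage1, stage2_removed)

  g <- grade_map[as.character(after2)]
  conserved <- after2[!is.na(g) & g == excluded_grade]
  unknown <- after2[is.na(g)]
  if (length(unknown)) {
    notes <- c(notes, sprintf(
      "residue(s) %s have no conservation grade; policy '%s' applied",
      paste(unknown, collapse = ", "), missing_grade))
  }
  stage3_removed <- if (missing_grade == "drop") union(conserved, unknown) else conserved
  final <- setdiff(after2, stage3_removed)

  removals <- rbind(
    if (length(setdiff(input, stage1)))
      data.frame(residue = setdiff(input, stage1), stage = 1L,
                 reason = sprintf("delta RMSF <= %g A", threshold)),
    if (length(stage2_removed))
      data.frame(residue = stage2_removed, stage = 2L,
                 reason = "prolonged substrate contact"),
    if (length(stage3_removed))
      data.frame(residue = stage3_removed, stage = 3L,
                 reason = ifelse(stage3_removed %in% conserved,
                                 sprintf("conservation grade = %d", excluded_grade),
                                 "conservation grade missing (policy drop)"))
  )
  if (is.null(removals)) {
    removals <- data.frame(residue = integer(), stage = integer(),
                           reason = character())
  }

  structure(
    list(input_residues = input,
         stage1_pass = sort(stage1),
         stage2_removed = sort(stage2_removed),
         stage3_removed = sort(stage3_removed),
         final_candidates = sort(final),
         removals = removals[order(removals$stage, removals$residue), ],
         notes = notes,
         parameters = list(threshold = threshold,
                           excluded_grade = as.integer(excluded_grade),
                           missing_grade = missing_grade)),
    class = "selection_report"
  )
}

.grade_lookup <- function(grades) {
  if (is.data.frame(grades)) {
    gcol <- if ("grade" %in% names(grades)) "grade" else "conservation"
    if (!gcol %in% names(grades) || !"residue" %in% names(grades)) {
      stop_msc("grades data frame needs columns 'residue' and 'grade'/'conservation'",
               class = "msc_value_error")
    }
    stats::setNames(as.integer(grades[[gcol]]), as.character(grades$residue))
  } else {
    if (is.null(names(grades))) {
      stop_msc("grades vector must be named by residue id", class = "msc_value_error")
    }
    stats::setNames(as.integer(grades), names(grades))
  }
}

#' @export
print.selection_report <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("Candidate-site selection (threshold %g A, excluded grade %d)\n",
              p$threshold, p$excluded_grade))
  cat(sprintf("  input residues:      %d\n", length(x$input_residues)))
  cat(sprintf("  stage 1 (flexible):  %d pass\n", length(x$stage1_pass)))
  cat(sprintf("  stage 2 (contacts):  %d removed\n", length(x$stage2_removed)))
  cat(sprintf("  stage 3 (conserved): %d removed\n", length(x$stage3_removed)))
  cat(sprintf("  final candidates:    %d  {%s}\n", length(x$final_candidates),
              paste(x$final_candidates, collapse = ", ")))
  for (n in x$notes) cat("  note:", n, "\n")
  invisible(x)
}
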