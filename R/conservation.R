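# Entropy-based per-column conservation scoring of a multiple sequence
# alignment, binned onto the 1-9 grade scale used for the strict-conservation
# exclusion (grade 9 = strictly conserved). The scorer is anchored
# absolutely: an all-identical column scores 1.0 (grade 9) and a uniform
# column 0.0 (grade 1), so the grade-9 exclusion rule is meaningful on any
# alignment regardless of its depth.

.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Raw per-column conservation scores
#'
#' For each alignment column, `s = 1 - H / ln(20)` where `H` is the Shannon
#' entropy of the amino-acid frequency distribution in that column, gaps
#' excluded. `s` is 1 for an invariant column and 0 for a uniform one.
#' All-gap columns get `NA`; columns with more than 50% gaps are flagged
#' low-confidence.
#'
#' @param msa `msc_msa` with at least 2 rows.
#' @return List with `scores` (numeric, `NA` for all-gap columns),
#'   `gap_fraction` and `low_confidence` (logical, gap fraction > 0.5).
#' @export
column_conservation <- function(msa) {
  stopifnot(inherits(msa, "msc_msa"))
  if (length(msa$ids) < 2L) {
    stop_msc("conservation scoring needs >= 2 sequences", class = "msc_value_error")
  }
  m <- msa_matrix(msa)
  ncolumns <- ncol(m)
  scores <- rep(NA_real_, ncolumns)
  gap_fraction <- numeric(ncolumns)
  for (j in seq_len(ncolumns)) {
    col <- m[, j]
    gap <- col == "-" | col == "."
    gap_fraction[j] <- mean(gap)
    aa <- col[!gap]
    if (length(aa) == 0L) next
    p <- table(aa) / length(aa)
    h <- -sum(p * log(p))
    scores[j] <- 1 - h / log(20)
  }
  list(scores = pmin(pmax(scores, 0), 1),
       gap_fraction = gap_fraction,
       low_confidence = gap_fraction > 0.5)
}

#' Bin raw conservation scores onto the 1-9 grade scale
#'
#' `grade = 1 + round(8 s)` with round-half-away-from-zero, so `s = 1`
#' (strictly conserved) maps to grade 9 and `s = 0` to grade 1. Missing
#' scores stay missing.
#'
#' @param raw_scores Numeric scores in `[0, 1]` (NA allowed).
#' @return Integer grades in 1..9 (NA where the score is missing).
#' @export
grade_conservation <- function(raw_scores) {
  ok <- !is.na(raw_scores)
  if (any(raw_scores[ok] < 0 | raw_scores[ok] > 1)) {
    stop_msc("raw conservation scores must lie in [0, 1]", class = "msc_value_error")
  }
  out <- rep(NA_integer_, length(raw_scores))
  out[ok] <- as.integer(1 + round_half_up(8 * raw_scores[ok]))
  out
}

#' Map alignment columns to structure residue ids via a reference row
#'
#' Column `i` of the reference sequence's ungapped positions is paired with
#' the `i`-th structure residue id; the reference's ungapped length must
#' equal the number of structure residues.
#'
#' @param msa `msc_msa`.
#' @param reference_id Id of the reference row in the alignment.
#' @param structure_ids Residue ids of the structure (author numbering).
#' @param scores Optional list from [column_conservation()] (computed if
#'   omitted).
#' @return Object of class `conservation_profile`: data frame with columns
#'   `residue`, `column`, `score`, `grade`, `low_confidence`.
#' @export
map_columns_to_residues <- function(msa, reference_id, structure_ids,
                                    scores = NULL) {
  stopifnot(inherits(msa, "msc_msa"))
  if (!reference_id %in% msa$ids) {
    stop_msc("reference id '%s' not in alignment", reference_id,
             class = "msc_value_error")
  }
  scores <- scores %||% column_conservation(msa)
  refseq <- strsplit(msa$seqs[[reference_id]], "")[[1]]
  cols <- which(refseq != "-" & refseq != ".")
  if (length(cols) != length(structure_ids)) {
    stop_msc("ungapped reference length (%d) != structure residue count (%d)",
             length(cols), length(structure_ids), class = "msc_mapping_error")
  }
  out <- data.frame(residue = as.integer(structure_ids),
                    column = cols,
                    score = scores$scores[cols],
                    grade = grade_conservation(scores$scores[cols]),
                    low_confidence = scores$low_confidence[cols])
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Conservation profile of a structure from an alignment
#'
#' Convenience wrapper: score columns, grade them, and map them onto
#' structure residue ids through the reference row.
#'
#' @inheritParams map_columns_to_residues
#' @return `conservation_profile` data frame.
#' @export
conservation_profile <- function(msa, reference_id, structure_ids) {
  map_columns_to_residues(msa, reference_id, structure_ids)
}
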