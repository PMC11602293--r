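# Readers and writers for the formats the screen touches: PDB structures
# (single and multi-model), a plain-text trajectory frames table, aligned
# multi-FASTA, and the tab-separated residue annotation table that carries
# per-residue RMSF at two temperatures, conservation grade and the
# substrate-contact flag.
#
# Conventions fixed here and relied on everywhere else:
#   * coordinates are in Angstrom,
#   * residue ids are 1-based author numbering and are never renumbered.

#' Read a protein structure from a PDB file
#'
#' Thin wrapper around [bio3d::read.pdb()] that preserves author residue
#' numbering and returns a light-weight atom table.
#'
#' @param path Path to a PDB file.
#' @param chain_filter Optional single chain identifier; only atoms of that
#'   chain are returned.
#' @return An object of class `msc_structure`: a list with `atoms` (data frame
#'   with columns `atom_name`, `residue_id`, `residue_name`, `chain`, `x`,
#'   `y`, `z`) and `residue_ids` (unique ids in file order).
#' @export
read_structure <- function(path, chain_filter = NULL) {
  if (!file.exists(path)) {
    stop_msc("structure file not found: %s", path, class = "msc_io_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
    error = function(e) {
      bad <- .first_bad_pdb_line(path)
      stop_msc("not a parseable PDB file: %s (first bad line %d: '%s')",
               path, bad$line, bad$text, class = "msc_format_error")
    }
  )
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) {
    bad <- .first_bad_pdb_line(path)
    stop_msc("no ATOM records in %s (first bad line %d: '%s')",
             path, bad$line, bad$text, class = "msc_format_error")
  }
  if (!is.null(chain_filter)) {
    at <- at[at$chain %in% chain_filter, , drop = FALSE]
    if (nrow(at) == 0L) {
      stop_msc("chain filter '%s' selects no atoms in %s",
               paste(chain_filter, collapse = ","), path,
               class = "msc_empty_selection_error")
    }
  }
  atoms <- data.frame(
    atom_name    = at$elety,
    residue_id   = as.integer(at$resno),
    residue_name = at$resid,
    chain        = at$chain,
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z)))) {
    stop_msc("non-finite coordinates in %s", path, class = "msc_format_error")
  }
  structure(
    list(atoms = atoms, residue_ids = unique(atoms$residue_id)),
    class = "msc_structure"
  )
}

.first_bad_pdb_line <- function(path) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (startsWith(ln, "ATOM") || startsWith(ln, "HETATM")) {
      xyz <- suppressWarnings(as.numeric(c(
        substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
      if (any(is.na(xyz))) return(list(line = i, text = ln))
    }
  }
  list(line = 1L,
       text = if (length(lines)) lines[1] else "<empty file>")
}

#' Read a coordinate trajectory
#'
#' Accepts either a multi-model PDB or the package's plain-text frames table
#' (header line `natoms nframes timestep_ps`, then one whitespace-separated
#' `x y z` triple per atom, frames concatenated).
#'
#' @param path Input file.
#' @param format One of `"auto"`, `"pdb"`, `"frames"`.
#' @param timestep Time between frames in ps (overrides the frames-table
#'   header when given; required metadata for PDB input, default 1).
#' @param temperature Temperature label in K stored with the ensemble.
#' @param residue_ids Optional residue ids for the atom set (defaults to
#'   the PDB numbering, or `1:natoms` for frames tables).
#' @return An object of class `msc_trajectory`: list with `coords` (array
#'   `nframes x natoms x 3`, Angstrom), `timestep` (ps), `temperature` (K)
#'   and `residue_ids`.
#' @export
read_trajectory <- function(path, format = c("auto", "pdb", "frames"),
                            timestep = NULL, temperature = NA_real_,
                            residue_ids = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L, warn = FALSE)
    format <- if (grepl("^(ATOM|HETATM|MODEL|HEADER|REMARK|CRYST|TITLE|EXPDTA)", first))
      "pdb" else "frames"
  }
  if (format == "pdb") {
    .read_trajectory_pdb(path, timestep %||% 1, temperature, residue_ids)
  } else {
    .read_trajectory_frames(path, timestep, temperature, residue_ids)
  }
}

.read_trajectory_pdb <- function(path, timestep, temperature, residue_ids) {
  # check per-MODEL atom counts ourselves so the error can cite the frame
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  if (length(model_starts) > 1L) {
    bounds <- c(model_starts, length(lines) + 1L)
    counts <- vapply(seq_along(model_starts), function(k) {
      sum(is_atom[bounds[k]:(bounds[k + 1L] - 1L)])
    }, integer(1))
    if (length(unique(counts)) > 1L) {
      bad <- which(counts != counts[1])[1]
      stop_msc("inconsistent atom count in frame %d (%d atoms vs %d in frame 1)",
               bad, counts[bad], counts[1], class = "msc_structural_mismatch_error")
    }
  }
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natoms <- ncol(xyz) / 3L
  nframes <- nrow(xyz)
  coords <- array(NA_real_, dim = c(nframes, natoms, 3L))
  for (f in seq_len(nframes)) {
    coords[f, , ] <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
  }
  ids <- residue_ids %||% as.integer(pdb$atom$resno)
  msc_trajectory(coords, timestep = timestep, temperature = temperature,
                 residue_ids = ids)
}

.read_trajectory_frames <- function(path, timestep, temperature, residue_ids) {
  con <- file(path, "r")
  on.exit(close(con))
  header <- scan(con, what = numeric(), n = 3L, quiet = TRUE)
  if (length(header) != 3L || any(!is.finite(header)) ||
      header[1] < 1 || header[2] < 1) {
    stop_msc("bad frames-table header in %s (expected 'natoms nframes timestep_ps')",
             path, class = "msc_format_error")
  }
  natoms <- as.integer(header[1]); nframes <- as.integer(header[2])
  vals <- scan(con, what = numeric(), quiet = TRUE)
  if (length(vals) != natoms * nframes * 3L) {
    got_frames <- length(vals) / (natoms * 3)
    stop_msc(paste0("frames table %s truncated or ragged: expected %d frames x %d atoms, ",
                    "coordinate count corresponds to frame %s"),
             path, nframes, natoms, format(got_frames),
             class = "msc_structural_mismatch_error")
  }
  coords <- aperm(array(vals, dim = c(3L, natoms, nframes)), c(3L, 2L, 1L))
  msc_trajectory(coords,
                 timestep = timestep %||% header[3],
                 temperature = temperature,
                 residue_ids = residue_ids %||% seq_len(natoms))
}

#' Construct a trajectory ensemble
#'
#' @param coords Array `nframes x natoms x 3` (Angstrom).
#' @param timestep Time between frames, ps (> 0).
#' @param temperature Temperature label, K.
#' @param residue_ids Residue id per atom (author numbering).
#' @return `msc_trajectory` object.
#' @export
msc_trajectory <- function(coords, timestep = 1, temperature = NA_real_,
                           residue_ids = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 3L, dim(coords)[1] >= 1L)
  if (!is.numeric(timestep) || timestep <= 0) {
    stop_msc("timestep must be > 0", class = "msc_value_error")
  }
  residue_ids <- residue_ids %||% seq_len(dim(coords)[2])
  stopifnot(length(residue_ids) == dim(coords)[2])
  structure(
    list(coords = coords, timestep = timestep, temperature = temperature,
         residue_ids = as.integer(residue_ids)),
    class = "msc_trajectory"
  )
}

#' Write a trajectory as a plain-text frames table
#'
#' Inverse of [read_trajectory()] for the frames-table format. Coordinates
#' are written with full (`%.17g`) precision so write/read round-trips are
#' bit-exact.
#'
#' @param traj `msc_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "msc_trajectory"))
  d <- dim(traj$coords)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %.17g", d[2], d[1], traj$timestep), con)
  for (f in seq_len(d[1])) {
    writeLines(sprintf("%.17g %.17g %.17g",
                       traj$coords[f, , 1], traj$coords[f, , 2],
                       traj$coords[f, , 3]), con)
  }
  invisible(path)
}

#' Read an aligned multi-FASTA file
#'
#' Rows must all have the same aligned length; lowercase letters are
#' uppercased on read.
#'
#' @param path Aligned FASTA file.
#' @return An object of class `msc_msa`: list with `ids` and `seqs`
#'   (named character vector of equal-length aligned strings).
#' @export
read_msa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L) {
    stop_msc("no FASTA headers in %s", path, class = "msc_format_error")
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  bounds <- c(hdr, length(lines) + 1L)
  seqs <- vapply(seq_along(hdr), function(k) {
    body <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    if (bounds[k] + 1L > bounds[k + 1L] - 1L) "" else
      toupper(gsub("\\s", "", paste(body, collapse = "")))
  }, character(1))
  msc_msa(ids, seqs)
}

#' Construct an MSA object
#'
#' @param ids Sequence identifiers.
#' @param seqs Aligned sequences (equal length, residues plus `-` gaps).
#' @return `msc_msa` object.
#' @export
msc_msa <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    ref <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    off <- ids[lens != ref]
    stop_msc("alignment rows differ in length (expected %d): %s",
             ref, paste(off, collapse = ", "),
             class = "msc_alignment_length_error")
  }
  names(seqs) <- ids
  structure(list(ids = as.character(ids), seqs = toupper(seqs),
                 width = lens[1] %||% 0L),
            class = "msc_msa")
}

#' Write an MSA as aligned multi-FASTA
#'
#' @param msa `msc_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path) {
  stopifnot(inherits(msa, "msc_msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(msa$ids)) {
    writeLines(c(paste0(">", msa$ids[k]), msa$seqs[k]), con)
  }
  invisible(path)
}

# MSA as a character matrix (rows = sequences, cols = alignment columns)
msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(msa$seqs, "", fixed = TRUE))
  rownames(m) <- msa$ids
  m
}

#' Read a residue annotation table
#'
#' Tab-separated table with header
#' `residue  rmsf_low  rmsf_high  delta  conservation  contact` — the layout
#' of a per-residue screening table: RMSF at the low and high simulation
#' temperature, their difference, a 1-9 conservation grade (may be missing)
#' and a logical substrate-contact flag (may be missing, read as `FALSE`).
#' When all three RMSF columns are present the stored `delta` is checked
#' against `rmsf_high - rmsf_low`; a discrepancy above 0.001 Angstrom raises
#' a consistency warning (not an error).
#'
#' @param path TSV file.
#' @return A data frame of class `msc_residue_table`.
#' @export
read_residue_table <- function(path) {
  if (!file.exists(path)) {
    stop_msc("residue table not found: %s", path, class = "msc_io_error")
  }
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("residue", "rmsf_low", "rmsf_high", "delta", "conservation", "contact")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop_msc("residue table %s lacks column(s): %s", path,
             paste(missing_cols, collapse = ", "), class = "msc_format_error")
  }
  residue_table(df[need])
}

#' Construct / validate a residue annotation table
#'
#' @param df Data frame with columns `residue`, `rmsf_low`, `rmsf_high`,
#'   `delta`, `conservation`, `contact`.
#' @return The validated, typed data frame (class `msc_residue_table`).
#' @export
residue_table <- function(df) {
  if (nrow(df)) {
    df$residue <- as.integer(df$residue)
    if (anyDuplicated(df$residue)) {
      stop_msc("duplicate residue ids: %s",
               paste(unique(df$residue[duplicated(df$residue)]), collapse = ", "),
               class = "msc_value_error")
    }
    grade_raw <- df$conservation
    grade_num <- suppressWarnings(as.numeric(grade_raw))
    bad <- !is.na(grade_num) & (grade_num != floor(grade_num))
    if (any(bad)) {
      stop_msc("non-integer conservation grade at residue %s",
               paste(df$residue[bad], collapse = ", "), class = "msc_parse_error")
    }
    df$conservation <- as.integer(grade_num)
    out_of_range <- !is.na(df$conservation) &
      (df$conservation < 1L | df$conservation > 9L)
    if (any(out_of_range)) {
      stop_msc("conservation grade outside 1..9 at residue %s",
               paste(df$residue[out_of_range], collapse = ", "),
               class = "msc_value_error")
    }
    df$contact <- .as_flag(df$contact)
    for (cc in c("rmsf_low", "rmsf_high", "delta")) df[[cc]] <- as.numeric(df[[cc]])
    full <- !is.na(df$rmsf_low) & !is.na(df$rmsf_high) & !is.na(df$delta)
    mism <- full & abs(df$delta - (df$rmsf_high - df$rmsf_low)) > 1e-3
    if (any(mism)) {
      warning(sprintf(
        "delta column inconsistent with rmsf_high - rmsf_low (> 0.001 A) at residue %s",
        paste(df$residue[mism], collapse = ", ")), call. = FALSE)
    }
  } else {
    df <- data.frame(residue = integer(), rmsf_low = numeric(),
                     rmsf_high = numeric(), delta = numeric(),
                     conservation = integer(), contact = logical())
  }
  class(df) <- c("msc_residue_table", "data.frame")
  df
}

.as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- trimws(tolower(as.character(x)))
  x[is.na(x)] <- ""
  x %in% c("true", "t", "1", "yes", "hydrophobic", "contact")
}

#' Write a residue annotation table
#'
#' @param table `msc_residue_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_residue_table <- function(table, path) {
  df <- as.data.frame(table)
  df$contact <- ifelse(df$contact, "TRUE", "FALSE")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged dual-temperature screening table for nattokinase AprY
#'
#' Returns the path to (or the parsed contents of) the packaged 32-residue
#' annotation table around the AprY catalytic triad: per-residue RMSF from
#' 100-ns simulations at 298 K and 328 K, their difference, 1-9 conservation
#' grades, and the four residues with prolonged hydrophobic substrate
#' contacts during steered pulling (96, 126, 154, 222).
#'
#' @param parse If `TRUE` (default) return the parsed `msc_residue_table`,
#'   otherwise the file path.
#' @return Table or path.
#' @export
apry_site_table <- function(parse = TRUE) {
  path <- system.file("extdata", "apry_site_table.tsv", package = "mscscreen",
                      mustWork = TRUE)
  if (parse) read_residue_table(path) else path
}
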