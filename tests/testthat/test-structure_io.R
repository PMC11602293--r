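test_that("PDB read-back preserves author residue numbering and chains", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(p, residue_ids = c(32, 64, 221), resnames = c("ASP", "HIS", "SER"))
  s <- read_structure(p)
  expect_s3_class(s, "msc_structure")
  expect_identical(s$residue_ids, c(32L, 64L, 221L))
  expect_identical(s$atoms$residue_name, c("ASP", "HIS", "SER"))

  # numbering starting at 30 must survive untouched
  p2 <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(p2, residue_ids = 30:34)
  expect_identical(read_structure(p2)$residue_ids, 30:34)
})

test_that("chain filtering selects only the requested chain and errors when empty", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(p, residue_ids = 1:4, chains = c("A", "A", "B", "B"))
  sA <- read_structure(p, chain_filter = "A")
  expect_identical(sA$residue_ids, 1:2)
  expect_true(all(sA$atoms$chain == "A"))
  expect_error(read_structure(p, chain_filter = "Z"),
               class = "msc_empty_selection_error")
})

test_that("unparseable structure files raise a format error naming a line", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("ATOM      1  CA  ALA A   1        xx.x   0.000   0.000"), p)
  expect_error(read_structure(p), class = "msc_format_error")
  err <- tryCatch(read_structure(p), error = identity)
  expect_match(conditionMessage(err), "line 1")
})

test_that("multi-model PDB reads as stacked frames; ragged models are rejected", {
  p <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(p, residue_ids = 1:3, models = 2L)
  tr <- read_trajectory(p, temperature = 298)
  expect_s3_class(tr, "msc_trajectory")
  expect_identical(dim(tr$coords), c(2L, 3L, 3L))
  expect_equal(tr$coords[1, , ], tr$coords[2, , ])

  bad <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(p)
  writeLines(lines[-4], bad)      # drop one atom from model 1
  err <- tryCatch(read_trajectory(bad), error = identity)
  expect_s3_class(err, "msc_structural_mismatch_error")
  expect_match(conditionMessage(err), "frame")
})

test_that("frames-table parsing honours the declared shape", {
  p <- withr::local_tempfile(fileext = ".txt")
  vals <- seq_len(5 * 3 * 3)
  writeLines(c("3 5 2.5", paste(vals)), p)
  tr <- read_trajectory(p)
  expect_identical(dim(tr$coords), c(5L, 3L, 3L))
  expect_equal(tr$timestep, 2.5)
  expect_equal(tr$coords[1, 1, ], c(1, 2, 3))
  expect_equal(tr$coords[2, 1, ], c(10, 11, 12))

  writeLines(c("3 5 2.5", paste(vals[-1])), p)
  expect_error(read_trajectory(p), class = "msc_structural_mismatch_error")
})

test_that("trajectory write/read round-trips bit-exactly", {
  set.seed(11)
  coords <- array(rnorm(100 * 7 * 3), c(100, 7, 3))
  tr <- msc_trajectory(coords, timestep = 0.1, residue_ids = 11:17)
  p <- withr::local_tempfile(fileext = ".txt")
  write_trajectory(tr, p)
  back <- read_trajectory(p, residue_ids = 11:17)
  expect_identical(back$coords, tr$coords)
  expect_identical(back$timestep, tr$timestep)
})

test_that("aligned FASTA reading uppercases, validates, and round-trips", {
  p <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acDEFGhikl", ">b", "ACDEFGHIKL"), p)
  msa <- read_msa(p)
  expect_identical(unname(msa$seqs), c("ACDEFGHIKL", "ACDEFGHIKL"))
  expect_identical(msa$width, 10L)

  writeLines(c(">a", "ACDEF", ">b", "ACDEF", ">bad", "ACD"), p)
  err <- tryCatch(read_msa(p), error = identity)
  expect_s3_class(err, "msc_alignment_length_error")
  expect_match(conditionMessage(err), "bad")

  msa2 <- gen_msa(50, data.frame(modal_residue = rep("L", 12),
                                 modal_freq = 0.6), seed = 5)
  p2 <- withr::local_tempfile(fileext = ".fasta")
  write_msa(msa2, p2)
  expect_identical(read_msa(p2)$seqs, msa2$seqs)
})

test_that("the packaged screening table parses with the expected annotations", {
  tab <- apry_site_table()
  expect_s3_class(tab, "msc_residue_table")
  expect_identical(nrow(tab), 32L)
  expect_identical(tab$residue[tab$contact], c(96L, 126L, 154L, 222L))
  r67 <- tab[tab$residue == 67, ]
  expect_equal(r67$rmsf_high - r67$rmsf_low, r67$delta, tolerance = 1e-9)
})

test_that("residue-table validation: delta check, grades, round-trip", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue\trmsf_low\trmsf_high\tdelta\tconservation\tcontact",
               "67\t0.526\t1.368\t0.842\t7\tFALSE"), p)
  expect_silent(tab <- read_residue_table(p))
  expect_identical(tab$conservation, 7L)

  writeLines(c("residue\trmsf_low\trmsf_high\tdelta\tconservation\tcontact",
               "67\t0.526\t1.368\t0.80\t7\tFALSE"), p)
  expect_warning(read_residue_table(p), "inconsistent")

  writeLines(c("residue\trmsf_low\trmsf_high\tdelta\tconservation\tcontact",
               "67\t0.526\t1.368\t0.842\t7.5\tFALSE"), p)
  expect_error(read_residue_table(p), class = "msc_parse_error")

  # empty table is legal
  writeLines("residue\trmsf_low\trmsf_high\tdelta\tconservation\tcontact", p)
  expect_identical(nrow(read_residue_table(p)), 0L)

  # write/read round-trip on the packaged table
  out <- withr::local_tempfile(fileext = ".tsv")
  write_residue_table(apry_site_table(), out)
  expect_equal(as.data.frame(read_residue_table(out)),
               as.data.frame(apry_site_table()))
})
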