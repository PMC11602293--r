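# Fixture builders shared across test files. Everything is generated in
# code; nothing binary is stored.

# Minimal fixed-column PDB writer (CA-only), enough for read-back tests.
write_toy_pdb <- function(path, residue_ids, chains = "A",
                          resnames = "ALA", coords = NULL, models = 1L) {
  n <- length(residue_ids)
  chains <- rep_len(chains, n)
  resnames <- rep_len(resnames, n)
  coords <- coords %||% cbind(3.8 * seq_len(n), 0, 0)
  lines <- character(0)
  for (m in seq_len(models)) {
    if (models > 1L) lines <- c(lines, sprintf("MODEL     %d", m))
    lines <- c(lines, vapply(seq_len(n), function(i) {
      sprintf("ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
              i, resnames[i], chains[i], residue_ids[i],
              coords[i, 1], coords[i, 2], coords[i, 3])
    }, character(1)))
    if (models > 1L) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent superposition oracle: numerical search over Euler-angle
# rotations (centroids matched analytically), multi-start BFGS.
oracle_superpose_rmsd <- function(mobile, reference) {
  a <- sweep(mobile, 2, colMeans(mobile))
  b <- sweep(reference, 2, colMeans(reference))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((a %*% t(rot(ang)) - b)^2)))
  starts <- as.matrix(expand.grid(c(0, pi / 2, pi, 3 * pi / 2),
                                  c(0, pi / 2, pi), c(0, pi)))
  best <- Inf
  for (s in seq_len(nrow(starts))) {
    fit <- stats::optim(starts[s, ], obj, method = "BFGS",
                        control = list(reltol = 1e-14, maxit = 500))
    if (fit$value < best) best <- fit$value
  }
  best
}

# Free ligand, no receptor: the constant-acceleration reference system.
free_particle_system <- function(mass = 624.24) {
  build_system(NULL, data.frame(x = 0, y = 0, z = 0, mass = mass,
                                apolar = TRUE))
}

table1_comparison <- function() comparison_from_table(apry_site_table())
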