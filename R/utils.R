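# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Boltzmann constant in Da * A^2 / ps^2 / K (2018 CODATA, converted).
.kB <- 0.8314462618

# pm/ps^2 -> A/ps^2
.PM_PER_A <- 0.01

# Round half away from zero (deterministic monotone binning; base round()
# uses round-half-even which would make grade boundaries depend on parity).
round_half_up <- function(x) {
  s <- sign(x)
  s * floor(abs(x) + 0.5)
}

stop_msc <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "msc_error")))
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}
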