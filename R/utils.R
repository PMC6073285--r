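# Internal helpers: condition classes and scoped RNG seeding.

nmj_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nmjquant_error")))
}

nmj_io_error <- function(msg) nmj_stop(msg, "nmjquant_io_error")
nmj_config_error <- function(msg) nmj_stop(msg, "nmjquant_config_error")
nmj_validation_error <- function(msg) nmj_stop(msg, "nmjquant_validation_error")
nmj_placement_error <- function(msg) nmj_stop(msg, "nmjquant_placement_error")

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

# Derive a child seed (kept within 32-bit integer range).
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647L)
}
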