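# Classed conditions so callers (and the CLI exit-code contract) can tell
# bad arguments/parse failures (exit 2) from internal inconsistencies (exit 3).

rs_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "regscout_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

input_error <- function(msg) rs_stop(msg, "regscout_input_error")

parse_error <- function(msg) rs_stop(msg, c("regscout_parse_error", "regscout_input_error"))

consistency_error <- function(msg) rs_stop(msg, "regscout_consistency_error")

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
# Generators must be pure functions of their config (seed included).
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}
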