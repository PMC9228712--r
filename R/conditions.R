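# Classed conditions so callers and tests can distinguish failure modes.

ir_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "irfusion_error"),
                      call = call))
}

stop_invalid <- function(msg) ir_stop(msg, "irfusion_invalid_input")
stop_degenerate <- function(msg) ir_stop(msg, "irfusion_degenerate")
stop_rank <- function(msg) ir_stop(msg, "irfusion_rank_deficiency")
stop_alignment <- function(msg) ir_stop(msg, "irfusion_alignment")

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so simulation never perturbs a user's session.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}
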