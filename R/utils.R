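# Classed conditions so callers can distinguish failure modes.
stop_tieprof <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "tieprof_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

stop_parse <- function(msg) stop_tieprof(msg, "tieprof_parse_error")
stop_validation <- function(msg) stop_tieprof(msg, "tieprof_validation_error")
stop_config <- function(msg) stop_tieprof(msg, "tieprof_config_error")
stop_empty <- function(msg) stop_tieprof(msg, "tieprof_empty_error")

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.  `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
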