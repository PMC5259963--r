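# Classed conditions so callers can distinguish failure modes programmatically.

tb_stop <- function(class, msg) {
  stop(structure(
    list(message = msg, call = sys.call(-1)),
    class = c(class, "trabecula_error", "error", "condition")
  ))
}

tb_warn <- function(class, msg) {
  warning(structure(
    list(message = msg, call = sys.call(-1)),
    class = c(class, "trabecula_warning", "warning", "condition")
  ))
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
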