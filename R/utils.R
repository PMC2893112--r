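#' @keywords internal
"_PACKAGE"

# Classed error so callers and tests can catch specific failure modes,
# e.g. tryCatch(..., methscreen_no_normalization_signal = ...).
ms_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "methscreen_error")))
}

# Run code under a temporary RNG state so simulators are reproducible from
# their own seed without clobbering the caller's stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# p-values to 4 decimals, effect sizes (HR, AUC) to 2: the convention used
# for human-readable TSV report columns.
fmt_p <- function(p) formatC(p, format = "f", digits = 4)
fmt_est <- function(x) formatC(x, format = "f", digits = 2)
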