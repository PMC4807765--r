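# Classed conditions so the CLI can map failures to exit codes
# (input error -> 1, internal -> 2).

stop_input <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("crossclust_input_error", "crossclust_error",
                                "error", "condition")))
}

stop_config <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("crossclust_config_error",
                                "crossclust_input_error", "crossclust_error",
                                "error", "condition")))
}

stop_internal <- function(fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c("crossclust_internal_error", "crossclust_error",
                                "error", "condition")))
}

# Run `code` under a temporary RNG state; the caller's .Random.seed is
# untouched.  seed = NULL runs the code against the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

# Renumber integer labels so clusters are 1..k in order of first appearance.
relabel_first_appearance <- function(labels) {
  out <- match(labels, unique(labels))
  names(out) <- names(labels)
  out
}

is_whole <- function(x, tol = 1e-8) all(abs(x - round(x)) < tol)
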