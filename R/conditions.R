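# Classed conditions so callers can distinguish failure modes programmatically.

ms_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(paste0("memskin_", class), "memskin_error"),
                      call = call))
}

ms_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(paste0("memskin_", class), "memskin_warning")))
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. seed = NULL leaves the RNG stream alone.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    ms_stop(sprintf("`%s` must be a positive finite scalar (got %s)",
                    name, deparse(x)), "invalid_parameter")
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    ms_stop(sprintf("`%s` must be a non-negative finite scalar (got %s)",
                    name, deparse(x)), "invalid_parameter")
  }
  invisible(x)
}
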