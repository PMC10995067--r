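# Internal condition helpers.  Two broad families are distinguished so the
# command-line wrapper can map them onto distinct exit codes:
#   "config" -- bad user input / configuration (exit 2)
#   "model"  -- a statistical model cannot be fitted as requested (exit 3)
# A subclass can be attached for programmatic handling in tests.

stop_agemeta <- function(msg, type = c("model", "config"), subclass = NULL) {
  type <- match.arg(type)
  classes <- c(
    if (!is.null(subclass)) paste0("agemeta_", subclass, "_error"),
    paste0("agemeta_", type, "_error"),
    "agemeta_error", "error", "condition"
  )
  stop(structure(class = classes, list(message = msg, call = sys.call(-1))))
}

# Draw per-unit sub-seeds from a root seed.  Drawing all sub-seeds in one
# sample.int() call means unit j's stream depends only on the root seed and
# j, never on how much randomness other units consumed.
derive_seeds <- function(seed, n) {
  if (is.null(seed) || !is.finite(seed)) {
    stop_agemeta("a finite integer seed is required", "config")
  }
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
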