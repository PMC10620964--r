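# Internal helpers shared across modules.

# Validation failures get their own condition class so the CLI can map them
# to exit code 2 while genuine runtime errors exit 1.
abort_validation <- function(msg, call = sys.call(-1)) {
  stop(errorCondition(msg,
                      class = c("mplexvar_validation_error", "error", "condition"),
                      call = call))
}

is_validation_error <- function(e) inherits(e, "mplexvar_validation_error")

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package internals never perturb user
# randomness.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Locale-independent (byte order) string sort so node orderings, and with
# them output files, are identical across machines.
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(x) order(x, method = "radix")

# Full-precision number formatting so write/read round-trips are bit exact.
fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[x == round(x) & abs(x) < 1e15] <- sprintf("%.0f", x[x == round(x) & abs(x) < 1e15])
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
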