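#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG seed, restoring the caller's RNG state.
# All randomness in the package flows through this so that a master seed plus
# deterministic sub-seed offsets gives component-level reproducibility.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# Deterministic sub-seed for block `i` of a master seed; kept inside 32-bit
# integer range. Blocks are numbered per simulator/stage so a component can be
# re-simulated alone and match the full run.
sub_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 101L + as.numeric(i) * 99991) %% 2147483647)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# Structured log line to stderr; level gating via option stemomics.log_level.
log_msg <- function(level, fmt, ...) {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  threshold <- levels[[getOption("stemomics.log_level", "info")]]
  if (levels[[level]] >= threshold) {
    message(sprintf("[%s] %s", toupper(level), sprintf(fmt, ...)))
  }
  invisible(NULL)
}
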