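# internal helpers

.err <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "gapcanal_error")))
}

.warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "gapcanal_warning")))
}

# Evaluate code with a locally seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic sub-seed derivation (kept below 2^31).
.sub_seed <- function(seed, i, j = 0L) {
  as.integer((as.numeric(seed) * 48271 + 65537 * i + 257 * j) %% 2147483587)
}

# Low-discrepancy Halton sequence in [0,1]^d (deterministic multistart).
.halton <- function(n, d) {
  bases <- c(2, 3, 5, 7, 11, 13)[seq_len(d)]
  vdc <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / b
      r <- r + f * (i %% b)
      i <- i %/% b
    }
    r
  }
  sapply(bases, function(b) vapply(seq_len(n), vdc, numeric(1), b = b))
}

# scalar-or-function(t) -> function(t)
.as_time_fun <- function(x, what = "input") {
  if (is.function(x)) return(x)
  if (is.numeric(x) && length(x) == 1L) return(function(t) x)
  .err(paste0(what, " must be a single number or a function of time"),
       "gapcanal_invalid_input")
}
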