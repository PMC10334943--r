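`%||%` <- function(a, b) if (is.null(a)) b else a

# Parse a character vector of ISO-8601 dates; error names the table/column
# and the first offending row so bad input is locatable.
parse_dates <- function(x, table, column) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  out <- as.Date(rep(NA_real_, length(x)), origin = "1970-01-01")
  nonmiss <- !is.na(x) & nzchar(x)
  out[nonmiss] <- as.Date(x[nonmiss], format = "%Y-%m-%d")
  bad <- which(nonmiss & is.na(out))
  if (length(bad)) {
    stop(sprintf(
      "unparseable date in %s$%s at row %d (line %d of file): '%s'",
      table, column, bad[1], bad[1] + 1L, x[bad[1]]
    ), call. = FALSE)
  }
  out
}

stop_domain <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop_domain("'%s' must be a probability in [0, 1]", name)
  }
  invisible(x)
}

# Round half away from zero at `digits` decimals (base round() rounds half
# to even, which cannot reproduce conventionally rounded published values).
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

days_between <- function(later, earlier) as.integer(later) - as.integer(earlier)

# Deterministic per-stage substreams from one global seed: each named stage
# reseeds the base RNG with an offset, so changing one stage's draws does
# not perturb the others.
stream_seed <- function(seed, stream) {
  offsets <- c(
    person = 1L, observation_period = 2L, truth = 3L, visit = 4L,
    condition = 5L, drug = 6L, comorbidity = 7L, negatives = 8L,
    model = 9L, evaluation = 10L, bootstrap = 11L, anchors = 12L
  )
  k <- offsets[[stream]]
  (as.integer(seed) %% 1000000L) * 1000L + k * 97L
}

set_stream <- function(seed, stream) set.seed(stream_seed(seed, stream))
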