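# Internal helpers shared across modules.

# round-half-away-from-zero; edge counts are positive so this is floor(x + .5)
.round_half_up <- function(x) floor(x + 0.5)

# Deterministic sub-seed derivation so each randomized component (simulation,
# permutation, rewiring, attack orders) draws from its own named stream.
# Kept strictly below 2^31 - 1.
.sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 100003) %% 2147483647)
}

# trapezoidal integral of y over (possibly non-uniform) x
.trapz <- function(x, y) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 2) stop("need at least two grid points to integrate")
  sum(diff(x) * (y[-1] + y[-n]) / 2)
}

# full-precision number formatting that round-trips doubles bit-identically
.fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
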