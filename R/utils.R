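# internal helpers shared across modules

# Reverse complement of an uppercase ACGTN character string.
# Non-ACGT letters map to N (kept as ambiguity, never matchable).
rc_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  flipped <- chartr("ACGTN", "TGCAN", x)
  paste(rev(strsplit(flipped, "", fixed = TRUE)[[1L]]), collapse = "")
}

# Round half away from zero at `decimals` places.  Base round() is
# half-to-even; every reported percentage in this package uses the
# half-away convention because that is the one that reproduces the
# printed values from the printed counts.
round_half_away <- function(x, decimals = 0L) {
  f <- 10^decimals
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Uppercase a sequence and collapse any non-ACGT character to N.
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

# log(sum(exp(x))) without overflow/underflow for very negative x
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
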