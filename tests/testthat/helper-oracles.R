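# Independent oracles and random-case generators for the test suite.
# These deliberately share no code with the package implementation:
# the motif oracle enumerates every spacer assignment exhaustively via
# expand.grid, and the hypergeometric oracle sums exact binomial
# products (exact in double precision for N <= 25, since every
# binomial coefficient and product involved is < 2^53).

# exhaustively test `pattern` anchored at 0-based `pos`; returns NULL
# or list(offset, length, gap_lengths) for the lexicographically
# smallest matching spacer assignment
oracle_match_at <- function(pattern, seq, pos) {
  sv <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  blocks <- pattern$blocks
  gaps <- Filter(function(b) b$type == "gap", blocks)
  grids <- lapply(gaps, function(g) g$min:g$max)
  assignments <- if (length(grids) == 0L) list(integer(0)) else {
    gr <- do.call(expand.grid, rev(grids))  # rev + re-rev => row order is
    gr <- gr[, rev(seq_len(ncol(gr))), drop = FALSE]  # lexicographic
    gr <- gr[do.call(order, as.list(gr)), , drop = FALSE]
    lapply(seq_len(nrow(gr)), function(i) as.integer(gr[i, ]))
  }
  acgt <- c("A", "C", "G", "T")
  for (assign in assignments) {
    i <- pos + 1L
    gi <- 0L
    ok <- TRUE
    for (b in blocks) {
      if (b$type == "lit") {
        w <- nchar(b$bases)
        lit <- strsplit(b$bases, "", fixed = TRUE)[[1L]]
        if (i + w - 1L > length(sv) || !all(sv[i:(i + w - 1L)] == lit)) {
          ok <- FALSE; break
        }
        i <- i + w
      } else if (b$type == "choice") {
        if (i > length(sv) || !(sv[i] %in% b$set)) { ok <- FALSE; break }
        i <- i + 1L
      } else {
        gi <- gi + 1L
        g <- assign[gi]
        if (g > 0L) {
          if (i + g - 1L > length(sv) || !all(sv[i:(i + g - 1L)] %in% acgt)) {
            ok <- FALSE; break
          }
          i <- i + g
        }
      }
    }
    if (ok) {
      return(list(offset = pos, length = (i - 1L) - pos,
                  gap_lengths = assign))
    }
  }
  NULL
}

# all hits of `pattern` in `seq` by exhaustive per-position enumeration
oracle_scan <- function(pattern, seq) {
  n <- nchar(seq)
  hits <- list()
  for (pos in 0:n) {
    h <- oracle_match_at(pattern, seq, pos)
    if (!is.null(h)) hits[[length(hits) + 1L]] <- h
  }
  hits
}

# random pattern string with <= 4 blocks (first/last anchored), spacer
# bounds <= 3
random_pattern_spec <- function() {
  anchor <- function() {
    if (stats::runif(1) < 0.5) {
      paste(sample(c("A", "C", "G", "T"), sample(1:3, 1), replace = TRUE),
            collapse = "")
    } else {
      paste0("[", paste(sample(c("A", "C", "G", "T"), sample(2:3, 1)),
                        collapse = ""), "]")
    }
  }
  nb <- sample(1:4, 1)
  toks <- character(nb)
  for (i in seq_len(nb)) {
    toks[i] <- if (i %in% c(1L, nb) || stats::runif(1) < 0.5) anchor() else {
      lo <- sample(0:2, 1); hi <- lo + sample(0:2, 1)
      if (hi > 3) hi <- 3
      sprintf("N(%d,%d)", lo, hi)
    }
  }
  paste(toks, collapse = "")
}

random_seq <- function(n, p_n = 0.03) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(rep((1 - p_n) / 4, 4), p_n)), collapse = "")
}

# exact upper-tail hypergeometric via choose(); exact for N <= 25
exact_log10_sf <- function(k, n, K, N) {
  i <- max(0L, n + K - N):min(n, K)
  p <- sum(choose(K, i[i >= k]) * choose(N - K, n - i[i >= k])) /
    choose(N, n)
  log10(p)
}

# log10 P[X >= min(n, K)] computed with elementary log arithmetic
# (single hypergeometric term as a telescoping product), accurate at
# magnitudes far below double underflow without lgamma
extreme_tail_log10 <- function(n, K, N) {
  i <- 0:(n - 1L)
  sum(log10((K - i) / (N - i)))
}

# re-verify a scan_region hit by aligning the pattern's fixed blocks at
# the positions implied by the reported gap lengths
verify_hit <- function(pattern, seq, offset, gaps) {
  sv <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  i <- offset + 1L
  gi <- 0L
  for (b in pattern$blocks) {
    if (b$type == "lit") {
      lit <- strsplit(b$bases, "", fixed = TRUE)[[1L]]
      if (!all(sv[i:(i + length(lit) - 1L)] == lit)) return(FALSE)
      i <- i + length(lit)
    } else if (b$type == "choice") {
      if (!(sv[i] %in% b$set)) return(FALSE)
      i <- i + 1L
    } else {
      gi <- gi + 1L
      if (gaps[gi] < b$min || gaps[gi] > b$max) return(FALSE)
      i <- i + gaps[gi]
    }
  }
  TRUE
}
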