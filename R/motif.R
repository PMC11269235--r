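#' Compile a degenerate gapped DNA motif
#'
#' Parses a motif written in the bracket/gap notation used for upstream
#' regulatory elements in *C. elegans* (e.g. the DAF-3/SMAD binding site
#' `"GTCTA"`, the ~30-bp MSP-motif conserved sequence
#' `"CT[AT]TAA[AT]TTN(0,3)[AC]AN(0,2)TTTTG[CT]CATAA[TA]C[TC]"`, or the
#' E-box `"CASCTG"`) into an ordered block grammar that
#' [match_at()] and [scan_region()] evaluate exactly.
#'
#' Accepted tokens:
#' * `A`, `C`, `G`, `T` — literal bases;
#' * `[ACT]` or `[A/C/T]` — a choice among the listed bases at one position;
#' * IUPAC one-letter codes `S` (C/G), `W` (A/T), `Y` (C/T), `R` (A/G);
#' * `N(min,max)` or `N_min-max` — a bounded spacer of any bases;
#' * a bare `N` — a spacer of exactly one base.
#'
#' Adjacent literals are merged; adjacent spacers are pooled by summing
#' their bounds. The first and last blocks of a pattern may not be
#' spacers (an unanchored flank has no defined match extent).
#'
#' @param spec Pattern string in the notation above.
#' @param name Optional pattern name (defaults to the spec string).
#' @return An object of class `"motif_pattern"`: a list with elements
#'   `name`, `blocks` (list of literal/choice/gap blocks), `min_len` and
#'   `max_len` (the attainable match lengths).
#' @examples
#' p <- compile_pattern("CASCTG", name = "ebox")
#' p$min_len  # 6
#' msp <- compile_pattern(msp_motif_spec(), name = "msp")
#' c(msp$min_len, msp$max_len)  # 25 30
#' @seealso [scan_region()], [classify_pd_status()], [motif_catalog()]
#' @export
compile_pattern <- function(spec, name = spec) {
  stopifnot(is.character(spec), length(spec) == 1L, nzchar(spec))
  iupac <- list(S = c("C", "G"), W = c("A", "T"), Y = c("C", "T"), R = c("A", "G"))
  chars <- strsplit(spec, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  blocks <- list()
  i <- 1L
  bad <- function(tok, at) {
    stop(sprintf("malformed motif token '%s' at position %d in pattern '%s'",
                 tok, at, spec), call. = FALSE)
  }
  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("A", "C", "G", "T")) {
      blocks[[length(blocks) + 1L]] <- list(type = "lit", bases = ch)
      i <- i + 1L
    } else if (ch %in% names(iupac)) {
      blocks[[length(blocks) + 1L]] <- list(type = "choice", set = iupac[[ch]])
      i <- i + 1L
    } else if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) bad(substr(spec, i, n), i)
      inner <- chars[(i + 1L):(j - 1L)]
      inner <- inner[inner != "/"]
      if (length(inner) == 0L || !all(inner %in% c("A", "C", "G", "T")))
        bad(substr(spec, i, j), i)
      set <- unique(inner)
      blocks[[length(blocks) + 1L]] <-
        if (length(set) == 1L) list(type = "lit", bases = set)
        else list(type = "choice", set = set)
      i <- j + 1L
    } else if (ch == "N") {
      nxt <- if (i < n) chars[i + 1L] else ""
      if (nxt == "(") {
        j <- i + 1L
        while (j <= n && chars[j] != ")") j <- j + 1L
        if (j > n) bad(substr(spec, i, n), i)
        tok <- substr(spec, i, j)
        m <- regmatches(tok, regexec("^N\\(([0-9]+),([0-9]+)\\)$", tok))[[1L]]
        if (length(m) != 3L) bad(tok, i)
        lo <- as.integer(m[2L]); hi <- as.integer(m[3L])
        if (hi < lo) bad(tok, i)
        blocks[[length(blocks) + 1L]] <- list(type = "gap", min = lo, max = hi)
        i <- j + 1L
      } else if (nxt == "_") {
        m <- regmatches(substr(spec, i, n),
                        regexec("^N_([0-9]+)-([0-9]+)", substr(spec, i, n)))[[1L]]
        if (length(m) != 3L) bad(substr(spec, i, min(n, i + 5L)), i)
        lo <- as.integer(m[2L]); hi <- as.integer(m[3L])
        if (hi < lo) bad(m[1L], i)
        blocks[[length(blocks) + 1L]] <- list(type = "gap", min = lo, max = hi)
        i <- i + nchar(m[1L])
      } else {
        blocks[[length(blocks) + 1L]] <- list(type = "gap", min = 1L, max = 1L)
        i <- i + 1L
      }
    } else {
      bad(ch, i)
    }
  }
  if (length(blocks) == 0L) bad(spec, 1L)
  # merge adjacent literals and adjacent gaps
  merged <- list(blocks[[1L]])
  for (b in blocks[-1L]) {
    last <- merged[[length(merged)]]
    if (b$type == "lit" && last$type == "lit") {
      last$bases <- paste0(last$bases, b$bases)
      merged[[length(merged)]] <- last
    } else if (b$type == "gap" && last$type == "gap") {
      last$min <- last$min + b$min
      last$max <- last$max + b$max
      merged[[length(merged)]] <- last
    } else {
      merged[[length(merged) + 1L]] <- b
    }
  }
  if (merged[[1L]]$type == "gap" || merged[[length(merged)]]$type == "gap")
    stop(sprintf("pattern '%s' may not begin or end with a spacer", spec),
         call. = FALSE)
  blen <- function(b, which) switch(b$type,
    lit = nchar(b$bases), choice = 1L, gap = b[[which]])
  structure(
    list(name = name, blocks = merged,
         min_len = sum(vapply(merged, blen, 1L, which = "min")),
         max_len = sum(vapply(merged, blen, 1L, which = "max"))),
    class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  desc <- vapply(x$blocks, function(b) switch(b$type,
    lit = b$bases,
    choice = paste0("[", paste(b$set, collapse = ""), "]"),
    gap = sprintf("N(%d,%d)", b$min, b$max)), "")
  cat(sprintf("<motif_pattern '%s'>  %s  (match length %d-%d)\n",
              x$name, paste(desc, collapse = " "), x$min_len, x$max_len))
  invisible(x)
}

# recursive block matcher over a character vector; returns integer vector
# of chosen gap lengths, or NULL if no assignment matches.  Gap lengths
# are tried ascending, first gap first, so the first success is the
# lexicographically smallest (leftmost-shortest) assignment.
.match_blocks <- function(sv, i, blocks, bi) {
  if (bi > length(blocks)) return(integer(0))
  b <- blocks[[bi]]
  n <- length(sv)
  if (b$type == "lit") {
    w <- nchar(b$bases)
    if (i + w - 1L > n) return(NULL)
    lit <- strsplit(b$bases, "", fixed = TRUE)[[1L]]
    if (!all(sv[i:(i + w - 1L)] == lit)) return(NULL)
    .match_blocks(sv, i + w, blocks, bi + 1L)
  } else if (b$type == "choice") {
    if (i > n || !(sv[i] %in% b$set)) return(NULL)
    .match_blocks(sv, i + 1L, blocks, bi + 1L)
  } else {
    for (g in b$min:b$max) {
      if (i + g - 1L > n) break
      ok <- g == 0L ||
        all(sv[i:(i + g - 1L)] %in% c("A", "C", "G", "T"))
      if (ok) {
        rest <- .match_blocks(sv, i + g, blocks, bi + 1L)
        if (!is.null(rest)) return(c(g, rest))
      }
    }
    NULL
  }
}

#' Test a motif at one position of a sequence
#'
#' Attempts to anchor `pattern` at 0-based position `pos` of `seq`. A
#' match exists iff some assignment of spacer lengths (each within its
#' bounds) makes every fixed position agree with the sequence. When
#' several assignments match, the leftmost-shortest (lexicographically
#' smallest) one is reported. Bases outside `ACGT` — including `N` from
#' assembly gaps — satisfy no pattern position, not even spacers.
#'
#' @param pattern A [compile_pattern()] object.
#' @param seq Nucleotide string (uppercased on use).
#' @param pos 0-based start position, `0 <= pos <= nchar(seq)`.
#' @return `NULL` if there is no match, otherwise a list with `offset`
#'   (= `pos`), `length` (matched span) and `gap_lengths` (integer
#'   vector, one entry per spacer block).
#' @examples
#' match_at(compile_pattern("GTCTA"), "GTCTA", 0)$length  # 5
#' @export
match_at <- function(pattern, seq, pos) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  if (pos < 0 || pos > n) stop("pos out of range [0, nchar(seq)]")
  sv <- strsplit(seq, "", fixed = TRUE)[[1L]]
  gaps <- .match_blocks(sv, pos + 1L, pattern$blocks, 1L)
  if (is.null(gaps)) return(NULL)
  fixed <- pattern$min_len - sum(vapply(pattern$blocks, function(b)
    if (b$type == "gap") b$min else 0L, 1L))
  list(offset = as.integer(pos),
       length = as.integer(fixed + sum(gaps)),
       gap_lengths = as.integer(gaps))
}

# candidate start positions (1-based) where the first block can match,
# used to prune the per-position scan
.candidate_starts <- function(sv, first, min_len) {
  n <- length(sv)
  if (n < min_len) return(integer(0))
  last_start <- n - min_len + 1L
  allowed <- if (first$type == "lit") {
    lit <- strsplit(first$bases, "", fixed = TRUE)[[1L]]
    ok <- rep(TRUE, last_start)
    for (j in seq_along(lit)) {
      ok <- ok & sv[seq_len(last_start) + j - 1L] == lit[j]
    }
    ok
  } else {
    sv[seq_len(last_start)] %in% first$set
  }
  which(allowed)
}

#' Scan a region for all motif occurrences
#'
#' Reports one hit per distinct start position admitting a match
#' (overlapping hits allowed; per start, the leftmost-shortest spacer
#' assignment). Optionally also scans the reverse complement of the
#' region; those hits carry `strand = "-"` and offsets in
#' reverse-complement coordinates. For palindromic patterns a forward
#' and a reverse hit can describe the same locus; deduplication is left
#' to the caller.
#'
#' @param pattern A [compile_pattern()] object.
#' @param seq Region nucleotide string (e.g. one element of
#'   [extract_upstream()] output).
#' @param both_strands Also scan the reverse complement (default FALSE:
#'   upstream regions are already transcription-oriented).
#' @return A data.frame with columns `offset` (0-based), `length`,
#'   `strand` (`"+"` forward, `"-"` reverse complement of the region)
#'   and `gaps` (list column of spacer-length vectors), ordered by
#'   strand then offset. Zero rows when nothing matches.
#' @examples
#' scan_region(compile_pattern("CASCTG"), "AACAGCTGACACCTGA")$offset  # 2 9
#' @export
scan_region <- function(pattern, seq, both_strands = FALSE) {
  stopifnot(inherits(pattern, "motif_pattern"))
  seq <- normalize_seq(seq)
  scan1 <- function(s, strand) {
    sv <- strsplit(s, "", fixed = TRUE)[[1L]]
    starts <- .candidate_starts(sv, pattern$blocks[[1L]], pattern$min_len)
    hits <- list()
    for (st in starts) {
      gaps <- .match_blocks(sv, st, pattern$blocks, 1L)
      if (!is.null(gaps)) {
        fixed <- pattern$min_len - sum(vapply(pattern$blocks, function(b)
          if (b$type == "gap") b$min else 0L, 1L))
        hits[[length(hits) + 1L]] <- list(
          offset = st - 1L, length = as.integer(fixed + sum(gaps)),
          strand = strand, gaps = as.integer(gaps))
      }
    }
    hits
  }
  hits <- scan1(seq, "+")
  if (both_strands) hits <- c(hits, scan1(rc_string(seq), "-"))
  if (length(hits) == 0L) {
    return(data.frame(offset = integer(0), length = integer(0),
                      strand = character(0),
                      gaps = I(list())))
  }
  out <- data.frame(
    offset = vapply(hits, `[[`, 1L, "offset"),
    length = vapply(hits, `[[`, 1L, "length"),
    strand = vapply(hits, `[[`, "", "strand"))
  out$gaps <- I(lapply(hits, `[[`, "gaps"))
  out[order(out$strand, out$offset), , drop = FALSE]
}

#' Scan many upstream regions with many motifs
#'
#' Produces the per-gene hit table and, per pattern, the gene set of
#' motif-containing genes — the genome-wide tally that feeds
#' [enrichment_test()].
#'
#' @param patterns List of [compile_pattern()] objects (may be empty).
#' @param regions Upstream-region table from [extract_upstream()], or
#'   any data.frame with `gene_id` and `seq` columns (unique gene_id).
#' @param both_strands Passed to [scan_region()].
#' @return List with `hits` — data.frame (`gene_id`, `pattern`,
#'   `n_hits`, `offsets` and `lengths`, both comma-separated and
#'   0-based; one row per gene x pattern with at least one hit) — and
#'   `sets`, a named list of gene-id character vectors (one per
#'   pattern, possibly empty).
#' @export
scan_geneset <- function(patterns, regions, both_strands = FALSE) {
  stopifnot(is.data.frame(regions), all(c("gene_id", "seq") %in% names(regions)))
  if (anyDuplicated(regions$gene_id))
    stop("duplicate gene_id among regions: ",
         paste(unique(regions$gene_id[duplicated(regions$gene_id)]), collapse = ", "))
  sets <- list()
  rows <- list()
  for (p in patterns) {
    stopifnot(inherits(p, "motif_pattern"))
    carriers <- character(0)
    for (i in seq_len(nrow(regions))) {
      h <- scan_region(p, regions$seq[i], both_strands = both_strands)
      if (nrow(h) > 0L) {
        carriers <- c(carriers, regions$gene_id[i])
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = regions$gene_id[i], pattern = p$name,
          n_hits = nrow(h),
          offsets = paste(h$offset, collapse = ","),
          lengths = paste(h$length, collapse = ","))
      }
    }
    sets[[p$name]] <- carriers
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), pattern = character(0),
               n_hits = integer(0), offsets = character(0),
               lengths = character(0))
  list(hits = hits, sets = sets)
}

#' Classify genes by composite PD-motif content
#'
#' A gene's upstream region has the full PD motif iff it contains at
#' least one DAF-3/SMAD site *and* at least one conserved-sequence (MSP
#' motif) instance, anywhere in the region and in any order — the
#' list-intersection definition, with no spacing or adjacency
#' constraint between the two elements.
#'
#' @param regions Upstream-region table (`gene_id`, `seq`; unique ids).
#' @param daf3,conserved [compile_pattern()] objects; default to the
#'   catalog patterns.
#' @param both_strands Passed to [scan_region()].
#' @return data.frame with columns `gene_id`, `has_daf3`,
#'   `has_conserved`, `has_full_pd`.
#' @export
classify_pd_status <- function(regions,
                               daf3 = motif_catalog()$daf3,
                               conserved = motif_catalog()$msp,
                               both_strands = FALSE) {
  res <- scan_geneset(list(daf3, conserved), regions, both_strands = both_strands)
  data.frame(
    gene_id = regions$gene_id,
    has_daf3 = regions$gene_id %in% res$sets[[daf3$name]],
    has_conserved = regions$gene_id %in% res$sets[[conserved$name]],
    has_full_pd = regions$gene_id %in% res$sets[[daf3$name]] &
      regions$gene_id %in% res$sets[[conserved$name]])
}

#' Motif pattern strings used in postdauer ADL regulatory analysis
#'
#' `msp_motif_spec()` returns the ~30-bp conserved-sequence element
#' ("MSP motif") of the composite PD motif, with its two bounded
#' spacers; `motif_catalog()` compiles the standard patterns: the DAF-3/
#' SMAD binding site `GTCTA`, the MSP motif, the ADL-specific E-box
#' `CASCTG` and the modified E-box `CACGTG`.
#'
#' @return `msp_motif_spec()`: the pattern string. `motif_catalog()`: a
#'   named list of compiled `motif_pattern`s (`daf3`, `msp`, `ebox`,
#'   `ebox_cacgtg`).
#' @export
msp_motif_spec <- function() {
  "CT[AT]TAA[AT]TTN(0,3)[AC]AN(0,2)TTTTG[CT]CATAA[TA]C[TC]"
}

#' @rdname msp_motif_spec
#' @export
motif_catalog <- function() {
  list(daf3 = compile_pattern("GTCTA", name = "daf3"),
       msp = compile_pattern(msp_motif_spec(), name = "msp"),
       ebox = compile_pattern("CASCTG", name = "ebox"),
       ebox_cacgtg = compile_pattern("CACGTG", name = "ebox_cacgtg"))
}

#' Read motif definitions from a text file
#'
#' Each non-comment line is `name<TAB or spaces>pattern`; `#` starts a
#' comment.
#'
#' @param path File path.
#' @return Named list of compiled `motif_pattern` objects.
#' @export
read_motifs <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "[ \t]+")[[1L]]
    if (length(parts) != 2L)
      stop("motif line must be 'name pattern': ", ln)
    out[[parts[1L]]] <- compile_pattern(parts[2L], name = parts[1L])
  }
  out
}
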