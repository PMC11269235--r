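#' Read a counts table
#'
#' Tab-separated with columns `gene_id`, `length_nt`, then one integer
#' column per sample. Sample names of the form
#' `genotype_condition_repN` are parsed into the sample metadata when
#' they match; otherwise metadata fields are NA.
#'
#' @param path TSV file.
#' @return List with `gene_ids`, `lengths_nt`, `counts` (gene x sample
#'   integer matrix) and `samples` (data.frame: `sample`, `genotype`,
#'   `condition`, `replicate`).
#' @export
read_counts <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "length_nt") %in% names(tab)))
  cn <- setdiff(names(tab), c("gene_id", "length_nt"))
  counts <- as.matrix(tab[, cn, drop = FALSE])
  rownames(counts) <- tab$gene_id
  meta <- regmatches(cn, regexec("^(.+)_(.+)_rep([0-9]+)$", cn))
  samples <- data.frame(
    sample = cn,
    genotype = vapply(meta, function(m) if (length(m)) m[2L] else NA_character_, ""),
    condition = vapply(meta, function(m) if (length(m)) m[3L] else NA_character_, ""),
    replicate = vapply(meta, function(m) if (length(m)) as.integer(m[4L]) else NA_integer_, 1L))
  list(gene_ids = tab$gene_id, lengths_nt = stats::setNames(tab$length_nt, tab$gene_id),
       counts = counts, samples = samples)
}

#' Reads per kilobase of transcript per million mapped reads
#'
#' `RPKM[g, s] = counts[g, s] * 1e9 / (length_nt[g] * total[s])`, with
#' `total[s]` the column sum of `counts` unless explicit per-sample
#' totals are supplied. Per-million normalization makes each sample's
#' RPKM invariant under uniform read duplication.
#'
#' @param counts Gene x sample matrix of non-negative integers.
#' @param lengths_nt Per-gene transcript lengths in nucleotides (> 0).
#' @param totals Optional per-sample total read counts (> 0).
#' @return Gene x sample RPKM matrix.
#' @examples
#' rpkm(matrix(10), lengths_nt = 1000, totals = 1e6)  # 10
#' @export
rpkm <- function(counts, lengths_nt, totals = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (length(lengths_nt) != nrow(counts))
    stop("one length per gene required")
  if (any(lengths_nt <= 0)) stop("transcript lengths must be positive")
  if (is.null(totals)) totals <- colSums(counts)
  if (any(totals <= 0)) stop("zero total reads in a sample")
  sweep(counts / lengths_nt, 2L, totals, "/") * 1e9
}

#' Call expressed genes at an RPKM threshold
#'
#' A gene is expressed in a condition when its replicate-summarized
#' RPKM meets the threshold (default: mean across the condition's
#' replicates, >= 10 RPKM).
#'
#' @param rpkm_mat Gene x sample RPKM matrix (rownames = gene ids).
#' @param samples Column names (or indices) belonging to the condition.
#' @param condition Label for the resulting set.
#' @param threshold RPKM cutoff (default 10).
#' @param rule `">="` (default) or `">"`.
#' @param summarizer Replicate summarizer (default `mean`).
#' @return Object of class `expressed_set`: list with `condition`,
#'   `threshold`, `rule`, `rpkm` (the summarized per-gene values) and
#'   `members` (a [gene_set()]).
#' @export
call_expressed <- function(rpkm_mat, samples = seq_len(ncol(rpkm_mat)),
                           condition = "all", threshold = 10,
                           rule = c(">=", ">"), summarizer = mean) {
  rule <- match.arg(rule)
  sub <- rpkm_mat[, samples, drop = FALSE]
  if (ncol(sub) == 0L) stop("empty condition subset")
  summarized <- apply(sub, 1L, summarizer)
  keep <- if (rule == ">=") summarized >= threshold else summarized > threshold
  structure(
    list(condition = condition, threshold = threshold, rule = rule,
         rpkm = summarized,
         members = gene_set(condition, rownames(rpkm_mat)[keep])),
    class = "expressed_set")
}

#' @export
print.expressed_set <- function(x, ...) {
  cat(sprintf("<expressed_set '%s'> %d genes with summarized RPKM %s %g\n",
              x$condition, length(x$members$members), x$rule, x$threshold))
  invisible(x)
}

#' Read a differential-expression table
#'
#' Tab-separated `gene_id, direction, fdr` (header optional), one row
#' per gene; `direction` in `up`/`down`; `fdr` in `[0, 1]`.
#'
#' @param path TSV file.
#' @return data.frame with those three columns.
#' @export
read_de_table <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("^\\s*gene_id\\b", first)
  tab <- utils::read.table(path, header = header, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!header) names(tab) <- c("gene_id", "direction", "fdr")[seq_len(ncol(tab))]
  de_table(tab$gene_id, tab$direction, tab$fdr)
}

#' Validate a differential-expression table
#'
#' @param gene_id,direction,fdr Per-row fields; one row per gene,
#'   `direction` in `up`/`down`, `fdr` in `[0, 1]`.
#' @return data.frame with columns `gene_id`, `direction`, `fdr`.
#' @export
de_table <- function(gene_id, direction, fdr) {
  if (anyDuplicated(gene_id))
    stop("duplicate gene_id in DE table: ",
         paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  if (!all(direction %in% c("up", "down")))
    stop("unknown direction token: ",
         paste(unique(setdiff(direction, c("up", "down"))), collapse = ", "))
  if (any(is.na(fdr)) || any(fdr < 0 | fdr > 1))
    stop("fdr must lie in [0, 1]")
  data.frame(gene_id = as.character(gene_id),
             direction = as.character(direction), fdr = as.numeric(fdr))
}

#' Split a DE table into up/down gene sets at an FDR cutoff
#'
#' Membership requires `fdr < fdr_cutoff` (strict inequality).
#'
#' @param table A [de_table()] data.frame.
#' @param fdr_cutoff FDR cutoff (default 0.05).
#' @param prefix Name prefix for the resulting sets.
#' @return List of two [gene_set()]s, `up` and `down`.
#' @export
de_sets <- function(table, fdr_cutoff = 0.05, prefix = "de") {
  table <- de_table(table$gene_id, table$direction, table$fdr)
  sig <- table[table$fdr < fdr_cutoff, , drop = FALSE]
  list(up = gene_set(paste0(prefix, "_up"),
                     sig$gene_id[sig$direction == "up"]),
       down = gene_set(paste0(prefix, "_down"),
                       sig$gene_id[sig$direction == "down"]))
}
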