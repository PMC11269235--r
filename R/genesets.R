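#' Construct and read gene sets
#'
#' A gene set is a named, deduplicated collection of gene identifiers.
#' `read_gene_list()` reads the one-id-per-line plain-text dialect
#' (`#` comments allowed).
#'
#' @param name Set name (non-empty).
#' @param members Character vector of gene ids (deduplicated on
#'   construction).
#' @return Object of class `gene_set`: list with `name` and `members`.
#' @export
gene_set <- function(name, members) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  members <- unique(as.character(members))
  members <- members[!is.na(members) & nzchar(members)]
  structure(list(name = name, members = members), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set '%s'> %d members\n", x$name, length(x$members)))
  invisible(x)
}

#' @rdname gene_set
#' @param path Text file, one gene id per line.
#' @export
read_gene_list <- function(path, name = basename(path)) {
  lines <- trimws(sub("#.*$", "", readLines(path)))
  gene_set(name, lines[nzchar(lines)])
}

#' Write a gene set as a plain-text list
#'
#' @param set A [gene_set()].
#' @param path Output file.
#' @export
write_gene_list <- function(set, path) {
  stopifnot(inherits(set, "gene_set"))
  writeLines(set$members, path)
}

.members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

#' Overlap of two gene sets
#'
#' @param a,b [gene_set()] objects (or plain id vectors).
#' @return Named integer vector `c(k, only_a, only_b)`: the shared
#'   count and the exclusive counts (they sum to the union size).
#' @export
overlap <- function(a, b) {
  ma <- .members(a); mb <- .members(b)
  k <- length(intersect(ma, mb))
  c(k = k, only_a = length(ma) - k, only_b = length(mb) - k)
}

#' Percentage reports with half-away-from-zero rounding
#'
#' `percent_of_query()` is `100 k / n_query`; `jaccard_percent()` is
#' the intersection-over-union similarity `100 k / (a + b - k)` used to
#' compare expressed transcriptomes; `annotate_fraction()` is the
#' within-set functional breakdown (an alias of `percent_of_query`
#' retained for report labelling). All round half away from zero at
#' `decimals` places, the convention that reproduces printed values
#' from printed counts.
#'
#' @param k Overlap count.
#' @param n_query Query-set size (> 0).
#' @param decimals Decimal places in the report.
#' @return A percentage (numeric scalar).
#' @examples
#' percent_of_query(3652, 5908, 0)        # 62
#' jaccard_percent(5908, 6001, 5206, 1)   # 77.7
#' @export
percent_of_query <- function(k, n_query, decimals = 0L) {
  stopifnot(k >= 0, k <= n_query)
  if (n_query <= 0) stop("n_query must be positive")
  round_half_away(100 * k / n_query, decimals)
}

#' @rdname percent_of_query
#' @param size_a,size_b The two set sizes (`k <= min(size_a, size_b)`).
#' @export
jaccard_percent <- function(size_a, size_b, k, decimals = 1L) {
  stopifnot(k >= 0, k <= min(size_a, size_b))
  u <- size_a + size_b - k
  if (u <= 0) stop("degenerate zero union")
  round_half_away(100 * k / u, decimals)
}

#' @rdname percent_of_query
#' @param subset_count,set_count Counts for the within-set breakdown.
#' @export
annotate_fraction <- function(subset_count, set_count, decimals = 1L) {
  percent_of_query(subset_count, set_count, decimals)
}

# log10 of one hypergeometric pmf term P[X = i | n, K, N]
.log10_hyper_pmf <- function(i, n, K, N) {
  (lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)) / log(10)
}

#' Log-space hypergeometric tail probabilities
#'
#' Upper tail `P[X >= k]` (`log_hypergeom_sf`) and lower tail
#' `P[X <= k]` (`log_hypergeom_cdf`) for the hypergeometric
#' distribution of the overlap between a size-`n` query and a size-`K`
#' reference drawn from a population of `N` genes. Computed entirely in
#' log space via log-gamma and log-sum-exp, so magnitudes far below
#' double underflow (printed p-values of order 1e-1200 and beyond)
#' remain finite and accurate. `P[X >= 0]` is exactly 1 (log10 = 0).
#'
#' @param k Observed overlap, `0 <= k <= min(n, K)`.
#' @param n Query size; `K` reference size; `N` population size
#'   (`max(n, K) <= N`).
#' @return log10 of the tail probability (a number <= 0).
#' @examples
#' 10^log_hypergeom_sf(2, 3, 3, 6)   # 0.5
#' @export
log_hypergeom_sf <- function(k, n, K, N) {
  .check_hyper(k, n, K, N)
  if (k <= max(0L, n + K - N)) return(0)
  i <- k:min(n, K)
  log_sum_exp(.log10_hyper_pmf(i, n, K, N) * log(10)) / log(10)
}

#' @rdname log_hypergeom_sf
#' @export
log_hypergeom_cdf <- function(k, n, K, N) {
  .check_hyper(k, n, K, N)
  if (k >= min(n, K)) return(0)
  i <- max(0L, n + K - N):k
  log_sum_exp(.log10_hyper_pmf(i, n, K, N) * log(10)) / log(10)
}

.check_hyper <- function(k, n, K, N) {
  if (any(c(k, n, K, N) < 0) || k > min(n, K) || max(n, K) > N)
    stop("require 0 <= k <= min(n, K) and max(n, K) <= N")
}

#' Hypergeometric enrichment test between two gene sets
#'
#' Assembles the 2x2 overlap of `query` and `reference` within an
#' explicit `population` (no silent default: p-values are extremely
#' sensitive to the population size) and reports fold enrichment and
#' the one-sided hypergeometric tail in log10 space. Enriched sets
#' (observed >= expected, ties counted as enriched) use the upper tail
#' and `fold = k / expected`; depleted sets use the lower tail and the
#' "x-fold under enriched" convention `fold = expected / k` (infinite
#' when `k = 0`).
#'
#' @param query,reference,population [gene_set()] objects;
#'   `query` and `reference` must be subsets of `population`.
#' @return Object of class `enrichment_result`: list with
#'   `query_name`, `reference_name`, `k`, `n`, `K`, `N`, `expected`,
#'   `fold`, `direction` (`"enriched"`/`"depleted"`), `log10_p` and
#'   `p_display` (scientific notation rendered from `log10_p` without
#'   exponentiating).
#' @export
enrichment_test <- function(query, reference, population) {
  q <- .members(query); r <- .members(reference); pop <- .members(population)
  bad <- setdiff(c(setdiff(q, pop), setdiff(r, pop)), character(0))
  if (length(bad) > 0L)
    stop("ids outside population: ", paste(utils::head(bad, 10L), collapse = ", "))
  k <- length(intersect(q, r))
  n <- length(q); K <- length(r); N <- length(pop)
  expected <- n * K / N
  enriched <- k >= expected
  log10_p <- if (enriched) log_hypergeom_sf(k, n, K, N)
             else log_hypergeom_cdf(k, n, K, N)
  fold <- if (k == 0 && !enriched) Inf
          else if (expected == 0) NA_real_
          else if (enriched) k / expected else expected / k
  structure(
    list(query_name = if (inherits(query, "gene_set")) query$name else "query",
         reference_name = if (inherits(reference, "gene_set")) reference$name else "reference",
         k = k, n = n, K = K, N = N, expected = expected, fold = fold,
         direction = if (enriched) "enriched" else "depleted",
         log10_p = log10_p, p_display = p_display(log10_p)),
    class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "<enrichment_result> %s vs %s: k=%d (n=%d, K=%d, N=%d)\n  expected %.2f, %.2f-fold %s, p = %s\n",
    x$query_name, x$reference_name, x$k, x$n, x$K, x$N,
    x$expected, x$fold, sub("ed$", "ed", x$direction), x$p_display))
  invisible(x)
}

#' Render a log10 probability in scientific notation
#'
#' Produces `"m.me-XXX"` directly from `log10_p`, never exponentiating,
#' so p-values of order 1e-1200 display faithfully.
#'
#' @param log10_p log10 of a probability (<= 0).
#' @param digits Mantissa digits after the point.
#' @return Character scalar, e.g. `"5.5e-13"`; `"1"` when `log10_p`
#'   is 0.
#' @export
p_display <- function(log10_p, digits = 1L) {
  stopifnot(log10_p <= 0)
  if (log10_p == 0) return("1")
  e <- floor(log10_p)
  m <- round(10^(log10_p - e), digits)
  if (m >= 10) { m <- m / 10; e <- e + 1 }  # rounding carried the mantissa
  sprintf("%.*fe%d", digits, m, as.integer(e))
}

#' Partition differential expression by genotype dependence
#'
#' Given the up/down differentially expressed (DE) gene sets of a
#' wild-type and a mutant genotype, identifies the wild-type DE genes
#' whose differential expression depends on the mutated factor: those
#' not shared with the mutant's corresponding DE list. This is the set
#' subtraction behind statements like "101 genes require NRDE-3 for
#' their upregulation".
#'
#' @param wt_up,wt_down,mut_up,mut_down [gene_set()] objects; up and
#'   down must be disjoint within each genotype.
#' @return Object of class `dependence_partition`: list with the four
#'   input sizes, `shared_up`/`shared_down` overlap counts,
#'   `dependent_up`/`dependent_down` gene sets (wild-type-only members)
#'   and `percent_dependent` (share of all wild-type DE genes that are
#'   dependent, rounded half away from zero to 0 decimals).
#' @export
dependence_partition <- function(wt_up, wt_down, mut_up, mut_down) {
  wu <- .members(wt_up); wd <- .members(wt_down)
  mu <- .members(mut_up); md <- .members(mut_down)
  if (length(intersect(wu, wd)) > 0L)
    stop("wild-type up and down sets overlap")
  if (length(intersect(mu, md)) > 0L)
    stop("mutant up and down sets overlap")
  dep_up <- setdiff(wu, mu)
  dep_down <- setdiff(wd, md)
  n_wt <- length(wu) + length(wd)
  structure(
    list(n_wt_up = length(wu), n_wt_down = length(wd),
         n_mut_up = length(mu), n_mut_down = length(md),
         shared_up = length(intersect(wu, mu)),
         shared_down = length(intersect(wd, md)),
         dependent_up = gene_set("dependent_up", dep_up),
         dependent_down = gene_set("dependent_down", dep_down),
         percent_dependent = if (n_wt == 0) NA_real_ else
           round_half_away(100 * (length(dep_up) + length(dep_down)) / n_wt, 0L)),
    class = "dependence_partition")
}

#' @export
print.dependence_partition <- function(x, ...) {
  cat(sprintf(
    paste0("<dependence_partition>\n",
           "  up:   %d wild-type, %d shared -> %d dependent\n",
           "  down: %d wild-type, %d shared -> %d dependent\n",
           "  %s%% of wild-type DE genes are genotype-dependent\n"),
    x$n_wt_up, x$shared_up, length(x$dependent_up$members),
    x$n_wt_down, x$shared_down, length(x$dependent_down$members),
    format(x$percent_dependent)))
  invisible(x)
}

#' Tabulate enrichment results as a report row
#'
#' @param results A list of [enrichment_test()] results.
#' @return data.frame with columns `query`, `reference`, `k`, `n`, `K`,
#'   `N`, `expected`, `fold`, `direction`, `log10_p`, `p_display`.
#' @export
enrichment_report <- function(results) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r) data.frame(
    query = r$query_name, reference = r$reference_name,
    k = r$k, n = r$n, K = r$K, N = r$N, expected = r$expected,
    fold = r$fold, direction = r$direction,
    log10_p = r$log10_p, p_display = r$p_display)))
}
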