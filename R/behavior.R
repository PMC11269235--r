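#' Octanol avoidance index from six-sector plate counts
#'
#' The assay plate is divided into six equal sectors A-F, with the
#' stimulus (1-octanol) spotted at sector A and the solvent control
#' (ethanol) at sector F; worms start between C and D. The index is
#' `((A + B) - (E + F)) / N` with `N` the total over all six sectors,
#' so it is bounded in [-1, 1]; a negative value means the worms moved
#' away from the stimulus, i.e. avoidance.
#'
#' @param A,B,C,D,E,F Non-negative worm counts per sector; alternatively
#'   `A` may be a length-6 vector of all sectors.
#' @return The avoidance index.
#' @examples
#' avoidance_index(0, 0, 3, 3, 10, 14)  # -0.8
#' @export
avoidance_index <- function(A, B = NULL, C = NULL, D = NULL, E = NULL, F = NULL) {
  s <- if (is.null(B)) A else c(A, B, C, D, E, F)
  if (length(s) != 6L || any(is.na(s)) || any(s < 0))
    stop("need six non-negative sector counts A-F")
  N <- sum(s)
  if (N == 0) stop("no worms on the plate (N = 0)")
  unname(((s[1L] + s[2L]) - (s[5L] + s[6L])) / N)
}

#' Chemotaxis index from two-spot counts
#'
#' `(n_attractant - n_control) / n_total`; +1 is perfect attraction,
#' -1 perfect repulsion. `n_total` is the total number of worms on the
#' plate and may exceed the number scored at the two spots.
#'
#' @param n_attractant,n_control Worms within the scoring radius of the
#'   attractant and ethanol-control spots after 1 h.
#' @param n_total Total worms (>= `n_attractant + n_control`, > 0).
#' @return The chemotaxis index.
#' @examples
#' chemotaxis_index(30, 10, 100)  # 0.2
#' @export
chemotaxis_index <- function(n_attractant, n_control, n_total) {
  if (any(c(n_attractant, n_control, n_total) < 0))
    stop("counts must be non-negative")
  if (n_total == 0) stop("no worms on the plate (n_total = 0)")
  if (n_attractant + n_control > n_total)
    stop("scored worms exceed total")
  (n_attractant - n_control) / n_total
}

#' Fraction of tested worms showing an avoidance reversal
#'
#' A reversal is a backward motion of 1.5 body lengths within 4 s of
#' stimulus presentation.
#'
#' @param n_reversed Worms that reversed (`<= n_tested`).
#' @param n_tested Worms tested (> 0).
#' @return `n_reversed / n_tested`, in [0, 1].
#' @export
reversal_fraction <- function(n_reversed, n_tested) {
  if (n_tested <= 0) stop("n_tested must be positive")
  if (n_reversed < 0 || n_reversed > n_tested)
    stop("require 0 <= n_reversed <= n_tested")
  n_reversed / n_tested
}

#' Read a plate-assay table and compute per-trial indices
#'
#' The TSV has one row per trial with columns `strain`, `assay`
#' (`avoidance`, `chemotaxis` or `reversal`) and the raw counts for its
#' assay type (`A`-`F` sector counts; `n_attractant`, `n_control`,
#' `n_total`; or `n_reversed`, `n_tested`); unused columns may be
#' empty/NA.
#'
#' @param path Assay TSV.
#' @return data.frame of the input rows plus an `index` column.
#' @export
read_assays <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("strain", "assay") %in% names(tab)))
  tab$index <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    switch(r$assay,
      avoidance = avoidance_index(as.numeric(r[c("A", "B", "C", "D", "E", "F")])),
      chemotaxis = chemotaxis_index(r$n_attractant, r$n_control, r$n_total),
      reversal = reversal_fraction(r$n_reversed, r$n_tested),
      stop("unknown assay type: ", r$assay))
  }, numeric(1L))
  tab
}

#' Summarize per-trial indices by strain and assay
#'
#' Trials are the unit of replication; the summary is mean and SD of
#' the per-trial indices.
#'
#' @param assays Output of [read_assays()] (or any data.frame with
#'   `strain`, `assay`, `index`).
#' @return data.frame with `strain`, `assay`, `n_trials`, `mean_index`,
#'   `sd_index`.
#' @export
summarize_assays <- function(assays) {
  agg <- split(assays$index, list(assays$strain, assays$assay), drop = TRUE)
  out <- do.call(rbind, lapply(names(agg), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    data.frame(strain = parts[1L], assay = parts[2L],
               n_trials = length(agg[[nm]]),
               mean_index = mean(agg[[nm]]),
               sd_index = stats::sd(agg[[nm]]))
  }))
  rownames(out) <- NULL
  out
}
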