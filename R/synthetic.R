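#' Sample one instance of a motif's language
#'
#' Choice positions and spacer lengths/bases are drawn uniformly, so
#' the returned string is always accepted by [match_at()] at offset 0.
#'
#' @param pattern A [compile_pattern()] object.
#' @param seed Optional integer seed (set once at entry).
#' @return A nucleotide string of length in `[min_len, max_len]`.
#' @export
sample_motif_instance <- function(pattern, seed = NULL) {
  stopifnot(inherits(pattern, "motif_pattern"))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  paste(vapply(pattern$blocks, function(b) switch(b$type,
    lit = b$bases,
    choice = sample(b$set, 1L),
    gap = {
      g <- if (b$min == b$max) b$min else sample(b$min:b$max, 1L)
      if (g == 0L) "" else paste(sample(bases, g, replace = TRUE), collapse = "")
    }), ""), collapse = "")
}

# background sequence of n iid bases from freq (named A/C/G/T)
.bg_seq <- function(n, freq) {
  paste(sample(names(freq), n, replace = TRUE, prob = freq), collapse = "")
}

# plant instance strings at non-overlapping uniform offsets in a
# background string; returns list(seq, offsets) or NULL if they cannot
# be placed without overlap
.plant <- function(background, instances) {
  w <- nchar(background)
  offs <- integer(0)
  lens <- nchar(instances)
  if (sum(lens) > w) return(NULL)
  for (attempt in seq_len(200L)) {
    cand <- vapply(lens, function(l) sample.int(w - l + 1L, 1L) - 1L, 1L)
    ok <- TRUE
    if (length(cand) > 1L) {
      o <- order(cand)
      so <- cand[o]; sl <- lens[o]
      ok <- all(so[-1L] >= (so[-length(so)] + sl[-length(sl)]))
    }
    if (ok) { offs <- cand; break }
  }
  if (length(offs) == 0L && length(instances) > 0L) return(NULL)
  sv <- strsplit(background, "", fixed = TRUE)[[1L]]
  for (j in seq_along(instances)) {
    iv <- strsplit(instances[j], "", fixed = TRUE)[[1L]]
    sv[(offs[j] + 1L):(offs[j] + lens[j])] <- iv
  }
  list(seq = paste(sv, collapse = ""), offsets = offs)
}

#' Generate a synthetic genome with planted upstream motifs
#'
#' Builds a small genome (FASTA-writable contig map + gene table) whose
#' upstream windows are rejection-sampled to contain *exactly* the
#' planted motif instances: a region is resampled until, for every
#' configured pattern, the scanner's hit count equals the planting
#' count (this removes chance background occurrences and chance
#' junction matches, so recovery tests are exact). Genes alternate
#' between the two strands. Planting assignments for the DAF-3 site and
#' the MSP conserved sequence overlap in exactly `n_full_pd` genes
#' (composite PD-motif carriers) and are disjoint otherwise; other
#' patterns are assigned independently.
#'
#' @param n_genes Number of genes (default 500).
#' @param window Upstream window length in bp (default 500; must be at
#'   least the longest pattern).
#' @param planting Named numeric vector: per-pattern fraction of genes
#'   carrying the motif (values < 1) or absolute carrier counts
#'   (values >= 1). Names must be names of `patterns`.
#' @param patterns Named list of [compile_pattern()] objects (default
#'   [motif_catalog()]'s `daf3`, `msp` and `ebox`).
#' @param n_full_pd Number of genes planted with both a DAF-3 site and
#'   an MSP-motif instance (counted inside the two patterns' carrier
#'   counts).
#' @param copies Named integer vector: instances planted per carrier
#'   gene (default 1 for every pattern).
#' @param base_freq Background base composition (default uniform; pass
#'   an AT-rich vector to stress pattern specificity).
#' @param genes_per_contig Contig plan (default 50 genes per contig).
#' @param length_nt_range Range from which per-gene transcript lengths
#'   (for RPKM) are drawn uniformly.
#' @param max_attempts Rejection cap per region (default 1000).
#' @param seed Optional integer seed.
#' @param out_dir If non-NULL, writes `genome.fa`, `genes.tsv` and
#'   `truth.json` there.
#' @return List with `genome` (named contig map), `genes` (annotation
#'   data.frame), and `truth`: `planted` (data.frame `gene_id`,
#'   `pattern`, `offset`, `instance` — offsets are region-relative) and
#'   `sets` (named list of carrier gene-id vectors, one per pattern,
#'   plus `full_pd`).
#' @export
gen_genome <- function(n_genes = 500L, window = 500L,
                       planting = c(daf3 = 0.1, msp = 0.074, ebox = 0.1),
                       patterns = motif_catalog()[c("daf3", "msp", "ebox")],
                       n_full_pd = 0L,
                       copies = NULL,
                       base_freq = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                       genes_per_contig = 50L,
                       length_nt_range = c(500L, 3000L),
                       max_attempts = 1000L,
                       seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(planting) %in% names(patterns)),
            all(planting >= 0))
  maxlen <- max(vapply(patterns, `[[`, 1L, "max_len"))
  if (window < maxlen) stop("window must be >= the longest pattern")
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  n_carriers <- vapply(names(planting), function(p) {
    v <- planting[[p]]
    as.integer(if (v < 1) round(v * n_genes) else v)
  }, 1L)
  names(n_carriers) <- names(planting)
  if (is.null(copies)) copies <- stats::setNames(rep(1L, length(patterns)),
                                                names(patterns))
  # carrier assignment: daf3/msp overlap exactly in the full-PD genes
  carriers <- list()
  if (n_full_pd > 0L) {
    if (!all(c("daf3", "msp") %in% names(patterns)))
      stop("n_full_pd needs the daf3 and msp patterns")
    if (n_full_pd > min(n_carriers["daf3"] %||% 0L, n_carriers["msp"] %||% 0L))
      stop("n_full_pd exceeds a pattern's carrier count")
  }
  pd_genes <- if (n_full_pd > 0L) sample(gene_ids, n_full_pd) else character(0)
  pool <- setdiff(gene_ids, pd_genes)
  for (p in names(n_carriers)) {
    extra <- n_carriers[[p]] - if (p %in% c("daf3", "msp")) n_full_pd else 0L
    if (extra < 0L) extra <- 0L
    if (p %in% c("daf3", "msp")) {
      avail <- setdiff(pool, unlist(carriers[intersect(c("daf3", "msp"), names(carriers))]))
      chosen <- if (extra > 0L) sample(avail, extra) else character(0)
      carriers[[p]] <- c(pd_genes, chosen)
    } else {
      carriers[[p]] <- if (n_carriers[[p]] > 0L) sample(gene_ids, n_carriers[[p]])
                       else character(0)
    }
  }
  scan_counts <- function(seq) vapply(patterns, function(p)
    nrow(scan_region(p, seq)), 1L)
  planted_rows <- list()
  regions <- character(n_genes)
  for (i in seq_len(n_genes)) {
    gid <- gene_ids[i]
    mine <- names(carriers)[vapply(carriers, function(cc) gid %in% cc, TRUE)]
    want <- stats::setNames(rep(0L, length(patterns)), names(patterns))
    instances <- character(0); inst_pat <- character(0)
    for (p in mine) {
      k <- copies[[p]] %||% 1L
      want[p] <- k
      for (j in seq_len(k)) {
        instances <- c(instances, sample_motif_instance(patterns[[p]]))
        inst_pat <- c(inst_pat, p)
      }
    }
    done <- FALSE
    for (attempt in seq_len(max_attempts)) {
      pl <- .plant(.bg_seq(window, base_freq), instances)
      if (is.null(pl)) next
      if (identical(scan_counts(pl$seq), want)) {
        regions[i] <- pl$seq
        if (length(instances) > 0L)
          planted_rows[[length(planted_rows) + 1L]] <- data.frame(
            gene_id = gid, pattern = inst_pat, offset = pl$offsets,
            instance = instances)
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("rejection cap exceeded for gene ", gid,
           ": pattern too permissive for this background; ",
           "use a larger-entropy background or smaller planting fractions")
  }
  # assemble contigs; genes alternate strand
  n_contigs <- ceiling(n_genes / genes_per_contig)
  genome <- character(n_contigs)
  names(genome) <- sprintf("chrS%02d", seq_len(n_contigs))
  genes <- vector("list", n_genes)
  body_len <- 30L  # physical gene stub: start codon + 27 bp
  for (i in seq_len(n_genes)) {
    ci <- (i - 1L) %/% genes_per_contig + 1L
    strand <- if (i %% 2L == 1L) "+" else "-"
    cursor <- nchar(genome[ci])
    spacer <- .bg_seq(20L, base_freq)
    if (strand == "+") {
      atg_pos <- cursor + 20L + window
      genome[ci] <- paste0(genome[ci], spacer, regions[i], "ATG",
                           .bg_seq(body_len - 3L, base_freq))
    } else {
      atg_pos <- cursor + 20L + body_len - 1L
      genome[ci] <- paste0(genome[ci], spacer,
                           .bg_seq(body_len - 3L, base_freq), "CAT",
                           rc_string(regions[i]))
    }
    genes[[i]] <- data.frame(
      gene_id = gene_ids[i], chrom = names(genome)[ci], strand = strand,
      atg_pos = atg_pos,
      length_nt = sample(length_nt_range[1L]:length_nt_range[2L], 1L))
  }
  genes <- do.call(rbind, genes)
  planted <- if (length(planted_rows)) do.call(rbind, planted_rows) else
    data.frame(gene_id = character(0), pattern = character(0),
               offset = integer(0), instance = character(0))
  truth <- list(planted = planted,
                sets = c(lapply(carriers, sort),
                         list(full_pd = sort(pd_genes))))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome),
                                file.path(out_dir, "genome.fa"))
    utils::write.table(genes, file.path(out_dir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         dataframe = "columns")
  }
  list(genome = genome, genes = genes, truth = truth)
}

#' Simulate an RNA-seq count matrix with planted differential expression
#'
#' Counts are drawn negative-binomially around per-gene baseline means
#' scaled by per-sample library-size factors, for a genotype x
#' condition x replicate design (default 2 x 2 x 4). Planted DE genes
#' have their mean multiplied (up) or divided (down) by `fold_change`
#' in the second condition; in the second genotype only the
#' non-dependent share of the wild-type DE genes keeps its fold change,
#' emulating factor-dependent differential expression.
#'
#' @param n_genes Number of genes (default 6000).
#' @param n_up,n_down Planted up-/downregulated gene counts in the
#'   first (wild-type) genotype (defaults 116 and 595).
#' @param dependent_fraction Share of wild-type DE genes whose fold
#'   change is absent in the second genotype (default 0.9).
#' @param genotypes,conditions Labels (defaults `c("WT", "mut")`,
#'   `c("CON", "PD")`).
#' @param replicates Biological replicates per genotype x condition
#'   (default 4).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of
#'   per-gene baseline means.
#' @param dispersion Negative-binomial dispersion (> 0; variance =
#'   mu + dispersion * mu^2).
#' @param fold_change Planted fold change (default 4).
#' @param libsize_range Uniform range of per-sample library-size
#'   factors.
#' @param length_nt_range Uniform range of transcript lengths.
#' @param fdr_de,fdr_null Ranges from which truth-table FDR values are
#'   drawn for DE and non-DE genes (so [de_sets()] at 0.05 recovers the
#'   planted sets exactly).
#' @param seed Optional integer seed.
#' @param out_dir If non-NULL, writes `counts.tsv` and one
#'   `de_<genotype>.tsv` per genotype.
#' @return List with `counts` (matrix, columns
#'   `genotype_condition_repN`), `lengths_nt`, `samples` metadata,
#'   and `truth`: per-genotype DE tables (`de`) plus the planted
#'   up/down id vectors per genotype.
#' @export
gen_counts <- function(n_genes = 6000L, n_up = 116L, n_down = 595L,
                       dependent_fraction = 0.9,
                       genotypes = c("WT", "mut"),
                       conditions = c("CON", "PD"), replicates = 4L,
                       baseline_meanlog = log(200), baseline_sdlog = 1,
                       dispersion = 0.1, fold_change = 4,
                       libsize_range = c(0.8, 1.2),
                       length_nt_range = c(500L, 3000L),
                       fdr_de = c(1e-6, 0.049), fdr_null = c(0.05, 1),
                       seed = NULL, out_dir = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (n_up + n_down > n_genes) stop("more planted DE genes than genes")
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  lengths_nt <- stats::setNames(
    sample(length_nt_range[1L]:length_nt_range[2L], n_genes, replace = TRUE),
    gene_ids)
  base_mu <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  de_genes <- sample(gene_ids, n_up + n_down)
  up_wt <- de_genes[seq_len(n_up)]
  down_wt <- de_genes[n_up + seq_len(n_down)]
  dep_up <- sample(up_wt, round(dependent_fraction * n_up))
  dep_down <- sample(down_wt, round(dependent_fraction * n_down))
  up_by_gt <- list(up_wt, setdiff(up_wt, dep_up))
  down_by_gt <- list(down_wt, setdiff(down_wt, dep_down))
  names(up_by_gt) <- names(down_by_gt) <- genotypes
  cols <- expand.grid(replicate = seq_len(replicates),
                      condition = conditions, genotype = genotypes,
                      stringsAsFactors = FALSE)
  cols <- cols[, c("genotype", "condition", "replicate")]
  sample_names <- sprintf("%s_%s_rep%d", cols$genotype, cols$condition,
                          cols$replicate)
  counts <- matrix(0L, nrow = n_genes, ncol = nrow(cols),
                   dimnames = list(gene_ids, sample_names))
  libsize <- stats::runif(nrow(cols), libsize_range[1L], libsize_range[2L])
  for (j in seq_len(nrow(cols))) {
    mu <- base_mu
    if (cols$condition[j] == conditions[2L]) {
      gt <- cols$genotype[j]
      mu[gene_ids %in% up_by_gt[[gt]]] <-
        mu[gene_ids %in% up_by_gt[[gt]]] * fold_change
      mu[gene_ids %in% down_by_gt[[gt]]] <-
        mu[gene_ids %in% down_by_gt[[gt]]] / fold_change
    }
    counts[, j] <- stats::rnbinom(n_genes, size = 1 / dispersion,
                                  mu = mu * libsize[j])
  }
  truth_de <- lapply(genotypes, function(gt) {
    dirn <- ifelse(gene_ids %in% up_by_gt[[gt]], "up",
                   ifelse(gene_ids %in% down_by_gt[[gt]], "down", "up"))
    is_de <- gene_ids %in% c(up_by_gt[[gt]], down_by_gt[[gt]])
    fdr <- ifelse(is_de, stats::runif(n_genes, fdr_de[1L], fdr_de[2L]),
                  stats::runif(n_genes, fdr_null[1L], fdr_null[2L]))
    de_table(gene_ids, dirn, fdr)
  })
  names(truth_de) <- genotypes
  out <- list(counts = counts, lengths_nt = lengths_nt,
              samples = data.frame(sample = sample_names, cols),
              truth = list(de = truth_de, up = up_by_gt, down = down_by_gt))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    tab <- data.frame(gene_id = gene_ids, length_nt = lengths_nt, counts,
                      check.names = FALSE)
    utils::write.table(tab, file.path(out_dir, "counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (gt in genotypes)
      utils::write.table(truth_de[[gt]],
                         file.path(out_dir, sprintf("de_%s.tsv", gt)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Generate a DE-down set with a planted motif association
#'
#' Draws down-membership per gene with probabilities `p1` (motif
#' carriers) and `p0` (non-carriers) chosen so that the odds ratio
#' `p1/(1-p1) / (p0/(1-p0))` equals `odds_ratio` and the expected
#' down fraction equals `down_fraction`.
#'
#' @param universe_size Population size (default 5000).
#' @param motif_fraction Fraction of genes carrying the motif.
#' @param down_fraction Expected fraction of genes that are DE down.
#' @param odds_ratio Configured association odds ratio (> 0; 1 = null).
#' @param seed Optional integer seed.
#' @return List with gene sets `universe`, `motif`, `down`, the
#'   realized 2x2 `table` (motif x down), and the solved probabilities
#'   `p1`, `p0`.
#' @export
gen_association <- function(universe_size = 5000L, motif_fraction = 0.04,
                            down_fraction = 0.1, odds_ratio = 1,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (odds_ratio <= 0) stop("odds_ratio must be > 0")
  N <- as.integer(universe_size)
  m <- as.integer(round(motif_fraction * N))
  ids <- sprintf("u%05d", seq_len(N))
  motif <- sample(ids, m)
  p1_of <- function(p0) odds_ratio * p0 / (1 - p0 + odds_ratio * p0)
  f <- function(p0) (m * p1_of(p0) + (N - m) * p0) / N - down_fraction
  if (f(1e-12) > 0 || f(1 - 1e-12) < 0)
    stop("infeasible marginals for the requested odds ratio")
  p0 <- stats::uniroot(f, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  p1 <- p1_of(p0)
  is_motif <- ids %in% motif
  down <- ids[stats::runif(N) < ifelse(is_motif, p1, p0)]
  tab <- table(motif = factor(is_motif, c(TRUE, FALSE)),
               down = factor(ids %in% down, c(TRUE, FALSE)))
  list(universe = gene_set("universe", ids),
       motif = gene_set("motif", motif),
       down = gene_set("down", down),
       table = tab, p1 = p1, p0 = p0)
}

#' Simulate a behavioral assay with a known attraction parameter
#'
#' Six-sector plates place worms multinomially with mass
#' `(1 + theta)/2` split evenly over sectors A and B and
#' `(1 - theta)/2` over E and F; central sectors C and D receive zero
#' mass in the canonical model, so the expected avoidance index equals
#' `theta`. An optional `lingering` mass is diverted to C/D (split
#' evenly) to emulate worms that never commit, which shrinks the
#' expected index to `theta * (1 - lingering)`. Two-spot chemotaxis
#' plates score all worms, attractant-side with probability
#' `(1 + theta)/2`, giving expected index `theta`.
#'
#' @param theta Attraction parameter in `[-1, 1]` (negative = the
#'   stimulus is avoided).
#' @param n_worms Worms on the plate.
#' @param type `"avoidance"` (six-sector) or `"chemotaxis"` (two-spot).
#' @param lingering Mass diverted to central sectors (six-sector only).
#' @param seed Optional integer seed.
#' @return For `"avoidance"`: named length-6 vector of sector counts
#'   A-F. For `"chemotaxis"`: list with `n_attractant`, `n_control`,
#'   `n_total`.
#' @export
gen_assay <- function(theta, n_worms, type = c("avoidance", "chemotaxis"),
                      lingering = 0, seed = NULL) {
  type <- match.arg(type)
  if (!is.null(seed)) set.seed(seed)
  if (theta < -1 || theta > 1) stop("theta must lie in [-1, 1]")
  if (type == "avoidance") {
    p_ab <- (1 + theta) / 2 * (1 - lingering)
    p_ef <- (1 - theta) / 2 * (1 - lingering)
    probs <- c(A = p_ab / 2, B = p_ab / 2, C = lingering / 2,
               D = lingering / 2, E = p_ef / 2, F = p_ef / 2)
    stats::setNames(as.integer(stats::rmultinom(1L, n_worms, probs)),
                    names(probs))
  } else {
    n_at <- stats::rbinom(1L, n_worms, (1 + theta) / 2)
    list(n_attractant = n_at, n_control = n_worms - n_at,
         n_total = n_worms)
  }
}
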