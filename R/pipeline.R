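#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a named list), fills in the standard
#' defaults — 500 bp upstream window, RPKM >= 10 expression cutoff,
#' FDR < 0.05 — and collects *all* validation errors before failing,
#' so a bad config is reported in one pass. Unknown keys produce a
#' warning, not an error.
#'
#' Recognized keys: `genome` (FASTA path), `annotation` (path),
#' `annotation_dialect` (`gene-table`/`gff3`), `counts` (TSV path,
#' optional), `de_tables` (named map genotype -> TSV path, optional),
#' `motifs` (motif definition file, optional: defaults to
#' [motif_catalog()]), `window`, `rpkm_threshold`, `rpkm_rule`,
#' `fdr_cutoff`, `both_strands`, `seed`, `out_dir`.
#'
#' @param config Path to a YAML file, or a named list.
#' @return A validated config list of class `pipeline_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("genome", "annotation", "annotation_dialect", "counts",
             "de_tables", "motifs", "window", "rpkm_threshold", "rpkm_rule",
             "fdr_cutoff", "both_strands", "seed", "out_dir")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L)
    warning("ignoring unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(annotation_dialect = "gene-table", window = 500L,
                   rpkm_threshold = 10, rpkm_rule = ">=", fdr_cutoff = 0.05,
                   both_strands = FALSE, seed = 1L, out_dir = NULL)
  for (k in names(defaults)) config[[k]] <- config[[k]] %||% defaults[[k]]
  errors <- character(0)
  need_file <- function(key, required) {
    p <- config[[key]]
    if (is.null(p)) {
      if (required) errors <<- c(errors, sprintf("missing required path '%s'", key))
    } else if (!all(file.exists(unlist(p)))) {
      errors <<- c(errors, sprintf("path for '%s' does not exist: %s", key,
                                   paste(unlist(p)[!file.exists(unlist(p))],
                                         collapse = ", ")))
    }
  }
  need_file("genome", TRUE)
  need_file("annotation", TRUE)
  need_file("counts", FALSE)
  need_file("de_tables", FALSE)
  need_file("motifs", FALSE)
  if (!config$annotation_dialect %in% c("gene-table", "gff3"))
    errors <- c(errors, "annotation_dialect must be 'gene-table' or 'gff3'")
  if (!is.numeric(config$window) || config$window < 1)
    errors <- c(errors, "window must be a positive integer")
  if (!is.numeric(config$rpkm_threshold) || config$rpkm_threshold < 0)
    errors <- c(errors, "rpkm_threshold must be >= 0")
  if (!config$rpkm_rule %in% c(">=", ">"))
    errors <- c(errors, "rpkm_rule must be '>=' or '>'")
  if (!is.numeric(config$fdr_cutoff) || config$fdr_cutoff <= 0 ||
      config$fdr_cutoff > 1)
    errors <- c(errors, "fdr_cutoff must lie in (0, 1]")
  if (length(errors) > 0L)
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  structure(config, class = "pipeline_config")
}

# project a region-relative hit offset onto + strand genomic coordinates
.hit_to_genomic <- function(region_row, offset, length) {
  if (region_row$strand == "+") {
    s <- region_row$start + offset
  } else {
    s <- region_row$end - offset - length
  }
  c(start = s, end = s + length)
}

#' Run the composed regulatory-motif / transcriptome analysis
#'
#' Executes the full pipeline on one input bundle: upstream-region
#' extraction, motif scanning and PD-motif classification; RPKM
#' expression calls per genotype x condition (when counts are given);
#' DE-set construction and genotype dependence partitioning (when DE
#' tables for two genotypes are given, first genotype treated as wild
#' type); and hypergeometric enrichment of every motif gene set against
#' every DE set, with the annotated gene universe as the population.
#' All tables are returned, and written to `out_dir` (TSV/FASTA/BED
#' plus a `manifest.json` of input MD5 hashes and the resolved config)
#' when it is set. Any stage failure is reported with the stage name.
#'
#' @param config A [validate_config()] input (path or list).
#' @return Invisible list with elements `regions`, `scan` (hit table +
#'   motif gene sets), `pd_status`, `expressed` (list of
#'   [call_expressed()] results), `de` (per-genotype up/down sets),
#'   `partition` ([dependence_partition()] or NULL), `enrichment`
#'   (report data.frame), `manifest`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  set.seed(config$seed)
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir))
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  genome <- stage("genome", read_genome(config$genome))
  genes <- stage("annotation",
                 read_annotation(config$annotation, config$annotation_dialect))
  regions <- stage("regions", extract_upstream(genes, genome, config$window))
  if (!is.null(out_dir))
    write_regions(regions, file.path(out_dir, "regions.fa"),
                  file.path(out_dir, "regions.bed"))

  patterns <- stage("motifs", if (is.null(config$motifs)) motif_catalog()
                    else read_motifs(config$motifs))
  scan <- stage("scan", scan_geneset(patterns, regions,
                                     both_strands = config$both_strands))
  emit(scan$hits, "motif_hits.tsv")
  if (!is.null(out_dir) && nrow(scan$hits) > 0L) {
    bed <- do.call(rbind, lapply(seq_len(nrow(scan$hits)), function(i) {
      gid <- scan$hits$gene_id[i]
      rr <- regions[regions$gene_id == gid, ][1L, ]
      offs <- as.integer(strsplit(scan$hits$offsets[i], ",")[[1L]])
      lens <- as.integer(strsplit(scan$hits$lengths[i], ",")[[1L]])
      do.call(rbind, lapply(seq_along(offs), function(j) {
        o <- offs[j]
        g <- .hit_to_genomic(rr, o, lens[j])
        data.frame(chrom = rr$chrom, start = g[["start"]], end = g[["end"]],
                   name = paste(gid, scan$hits$pattern[i], sep = "|"),
                   score = 0L, strand = rr$strand)
      }))
    }))
    writeLines(sprintf("%s\t%d\t%d\t%s\t%d\t%s", bed$chrom, bed$start,
                       bed$end, bed$name, bed$score, bed$strand),
               file.path(out_dir, "motif_hits.bed"))
  }
  pd_status <- if (all(c("daf3", "msp") %in% names(patterns)))
    stage("pd_status", classify_pd_status(regions, patterns$daf3, patterns$msp,
                                          both_strands = config$both_strands))
  else NULL
  if (!is.null(pd_status)) emit(pd_status, "pd_status.tsv")

  expressed <- NULL
  if (!is.null(config$counts)) {
    cm <- stage("counts", read_counts(config$counts))
    rk <- stage("rpkm", rpkm(cm$counts, cm$lengths_nt[cm$gene_ids]))
    grp <- interaction(cm$samples$genotype, cm$samples$condition, drop = TRUE)
    expressed <- stage("expressed", lapply(levels(grp), function(g) {
      call_expressed(rk, cm$samples$sample[grp == g], condition = g,
                     threshold = config$rpkm_threshold,
                     rule = config$rpkm_rule)
    }))
    names(expressed) <- levels(grp)
    if (!is.null(out_dir))
      for (g in names(expressed))
        write_gene_list(expressed[[g]]$members,
                        file.path(out_dir, sprintf("expressed_%s.txt", g)))
  }

  de <- NULL; partition <- NULL
  if (!is.null(config$de_tables)) {
    de <- stage("de", lapply(config$de_tables, function(p)
      de_sets(read_de_table(p), config$fdr_cutoff)))
    names(de) <- names(config$de_tables)
    if (length(de) >= 2L) {
      partition <- stage("partition", dependence_partition(
        de[[1L]]$up, de[[1L]]$down, de[[2L]]$up, de[[2L]]$down))
      if (!is.null(out_dir)) {
        rep_df <- data.frame(
          metric = c("wt_up", "wt_down", "mut_up", "mut_down", "shared_up",
                     "shared_down", "dependent_up", "dependent_down",
                     "percent_dependent"),
          value = c(partition$n_wt_up, partition$n_wt_down,
                    partition$n_mut_up, partition$n_mut_down,
                    partition$shared_up, partition$shared_down,
                    length(partition$dependent_up$members),
                    length(partition$dependent_down$members),
                    partition$percent_dependent))
        emit(rep_df, "dependence_partition.tsv")
      }
    } else if (!is.null(out_dir)) {
      message("only one DE table configured; dependence partition skipped")
    }
  }

  enr <- NULL
  if (!is.null(de)) {
    population <- gene_set("annotated", genes$gene_id)
    results <- list()
    for (pn in names(scan$sets)) {
      motif_set <- gene_set(pn, intersect(scan$sets[[pn]], population$members))
      for (gt in names(de)) {
        for (dirn in c("up", "down")) {
          ds <- de[[gt]][[dirn]]
          ds <- gene_set(ds$name, intersect(ds$members, population$members))
          results[[length(results) + 1L]] <-
            enrichment_test(motif_set, ds, population)
        }
      }
    }
    enr <- stage("enrichment", enrichment_report(results))
    emit(enr, "enrichment.tsv")
  }

  inputs <- unlist(config[c("genome", "annotation", "counts", "de_tables",
                            "motifs")])
  # out_dir is a location, not an analysis parameter: keep it out of the
  # manifest so identical analyses produce identical manifests
  cfg_rec <- unclass(config)
  cfg_rec$out_dir <- NULL
  manifest <- list(
    inputs = as.list(tools::md5sum(inputs[!is.null(inputs)])),
    config = cfg_rec[!vapply(cfg_rec, is.null, TRUE)])
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE)

  invisible(list(regions = regions, scan = scan, pd_status = pd_status,
                 expressed = expressed, de = de, partition = partition,
                 enrichment = enr, manifest = manifest))
}
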