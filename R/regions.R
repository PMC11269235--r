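#' Read a genome FASTA into a contig map
#'
#' @param path FASTA file.
#' @return Named character vector, one uppercase sequence per contig
#'   (names truncated at the first whitespace); bases outside ACGT
#'   become `N`.
#' @export
read_genome <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- normalize_seq(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Read a gene annotation
#'
#' Two dialects are supported. `"gene-table"`: a whitespace-separated
#' table with columns `gene_id, chrom, strand, atg_pos, length_nt`
#' (header line optional; `atg_pos` is the 0-based genomic coordinate of
#' the first base of the start codon; `length_nt` is the transcript
#' length used for RPKM and may be omitted). `"gff3"`: standard GFF3
#' (1-based inclusive, converted on read); `atg_pos` is taken from the
#' gene's CDS records — the 5'-most CDS coordinate on `+` genes and the
#' 3'-most on `-` genes.
#'
#' Records with a missing strand or coordinate are rejected with a
#' warning; the count of rejected records is attached as
#' `attr(, "rejected")`. A duplicated `gene_id` is a hard error.
#'
#' @param path Annotation file.
#' @param dialect `"gene-table"` or `"gff3"`.
#' @return data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `atg_pos` (0-based), `length_nt` (NA when not provided).
#' @export
read_annotation <- function(path, dialect = c("gene-table", "gff3")) {
  dialect <- match.arg(dialect)
  if (dialect == "gene-table") {
    first <- readLines(path, n = 1L)
    header <- grepl("^\\s*gene_id\\b", first)
    tab <- utils::read.table(path, header = header, stringsAsFactors = FALSE,
                             comment.char = "#")
    if (!header) {
      if (ncol(tab) < 4L || ncol(tab) > 5L)
        stop("gene table needs 4-5 columns: gene_id, chrom, strand, atg_pos[, length_nt]")
      names(tab) <- c("gene_id", "chrom", "strand", "atg_pos",
                      "length_nt")[seq_len(ncol(tab))]
    }
    if (!all(c("gene_id", "chrom", "strand", "atg_pos") %in% names(tab)))
      stop("gene table needs columns gene_id, chrom, strand, atg_pos")
    if (!"length_nt" %in% names(tab)) tab$length_nt <- NA_real_
    ok <- tab$strand %in% c("+", "-") & !is.na(tab$atg_pos) & tab$atg_pos >= 0
    rejected <- sum(!ok)
    if (rejected > 0L)
      warning(sprintf("%d annotation record(s) rejected (missing strand or coordinate)",
                      rejected))
    genes <- tab[ok, c("gene_id", "chrom", "strand", "atg_pos", "length_nt")]
  } else {
    gr <- rtracklayer::import(path, format = "gff3")
    cds <- gr[gr$type == "CDS"]
    id <- if (!is.null(cds$gene_id)) as.character(cds$gene_id)
      else if (!is.null(cds$ID)) as.character(cds$ID)
      else vapply(cds$Parent, function(p) if (length(p)) p[[1L]] else NA_character_, "")
    strand <- as.character(GenomicRanges::strand(cds))
    df <- data.frame(gene_id = id,
                     chrom = as.character(GenomicRanges::seqnames(cds)),
                     strand = strand,
                     start = GenomicRanges::start(cds),
                     end = GenomicRanges::end(cds),
                     stringsAsFactors = FALSE)
    ok <- df$strand %in% c("+", "-") & !is.na(df$gene_id) & !is.na(df$start)
    rejected <- sum(!ok)
    if (rejected > 0L)
      warning(sprintf("%d annotation record(s) rejected (missing strand or coordinate)",
                      rejected))
    df <- df[ok, , drop = FALSE]
    genes <- do.call(rbind, lapply(split(df, df$gene_id), function(g) {
      data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
                 strand = g$strand[1L],
                 atg_pos = if (g$strand[1L] == "+") min(g$start) - 1L
                           else max(g$end) - 1L,
                 length_nt = sum(g$end - g$start + 1L))
    }))
    rownames(genes) <- NULL
    genes <- genes[order(match(genes$gene_id, unique(df$gene_id))), , drop = FALSE]
  }
  dup <- unique(genes$gene_id[duplicated(genes$gene_id)])
  if (length(dup) > 0L)
    stop("duplicate gene_id in annotation: ", paste(dup, collapse = ", "))
  rownames(genes) <- NULL
  attr(genes, "rejected") <- rejected
  genes
}

#' Extract strand-aware upstream regulatory regions
#'
#' For each gene, the `window` bases immediately 5' of the start codon:
#' on `+` genes the genomic interval `[max(0, atg_pos - window),
#' atg_pos)` as written; on `-` genes `[atg_pos + 1, min(L, atg_pos + 1
#' + window))` reverse-complemented, so every returned sequence reads in
#' the direction of transcription and ends one base before the A of
#' ATG. The start codon itself is never included. Genes nearer than
#' `window` to the contig edge yield a shorter region with
#' `truncated = TRUE`; a gene with zero available upstream bases is an
#' error (distinct from truncation).
#'
#' @param genes Annotation data.frame from [read_annotation()] (or any
#'   data.frame with `gene_id`, `chrom`, `strand`, `atg_pos`).
#' @param genome Named contig map from [read_genome()].
#' @param window Upstream window in bp (default 500; must be >= 1).
#' @return data.frame of class `upstream_regions` with columns
#'   `gene_id`, `chrom`, `start`, `end` (0-based half-open, + strand of
#'   the contig), `strand`, `truncated`, `seq`.
#' @export
extract_upstream <- function(genes, genome, window = 500L) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "strand", "atg_pos") %in% names(genes)))
  window <- as.integer(window)
  if (is.na(window) || window < 1L) stop("window must be >= 1")
  out <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (!g$chrom %in% names(genome))
      stop("unknown contig '", g$chrom, "' for gene ", g$gene_id)
    contig <- genome[[g$chrom]]
    L <- nchar(contig)
    if (g$atg_pos < 0 || g$atg_pos >= L)
      stop("atg_pos out of contig range for gene ", g$gene_id)
    if (g$strand == "+") {
      start <- max(0L, g$atg_pos - window)
      end <- g$atg_pos
      if (end - start <= 0L)
        stop("gene ", g$gene_id, " has zero upstream bases on its contig")
      seq <- substr(contig, start + 1L, end)
    } else {
      start <- g$atg_pos + 1L
      end <- min(L, g$atg_pos + 1L + window)
      if (end - start <= 0L)
        stop("gene ", g$gene_id, " has zero upstream bases on its contig")
      seq <- rc_string(substr(contig, start + 1L, end))
    }
    out[[i]] <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                           start = as.integer(start), end = as.integer(end),
                           strand = g$strand,
                           truncated = (end - start) < window,
                           seq = seq)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("upstream_regions", "data.frame")
  res
}

#' Write upstream regions as FASTA and BED6
#'
#' FASTA headers are gene ids; BED rows are the 0-based half-open
#' genomic intervals with the gene's strand (score column 0). A
#' round-trip through [read_regions_fasta()] reproduces the sequences
#' exactly.
#'
#' @param regions [extract_upstream()] output (non-empty).
#' @param fasta_out,bed_out Output paths (`NULL` to skip one of them).
#' @return Invisibly, the region table.
#' @export
write_regions <- function(regions, fasta_out = NULL, bed_out = NULL) {
  stopifnot(is.data.frame(regions))
  if (nrow(regions) == 0L) stop("no regions to write")
  if (!is.null(fasta_out)) {
    ss <- Biostrings::DNAStringSet(stats::setNames(regions$seq, regions$gene_id))
    Biostrings::writeXStringSet(ss, fasta_out)
  }
  if (!is.null(bed_out)) {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     regions$chrom, regions$start, regions$end,
                     regions$gene_id, regions$strand)
    writeLines(lines, bed_out)
  }
  invisible(regions)
}

#' Read a region FASTA back into a region table
#'
#' @param path FASTA written by [write_regions()] (or any FASTA whose
#'   headers are gene ids).
#' @return data.frame with `gene_id` and `seq` columns, scannable by
#'   [scan_geneset()].
#' @export
read_regions_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  data.frame(gene_id = sub("\\s.*$", "", names(ss)),
             seq = as.character(ss))
}
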