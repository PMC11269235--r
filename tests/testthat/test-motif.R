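test_that("pattern compilation computes length bounds and rejects bad tokens", {
  p <- compile_pattern("GTCTA")
  expect_length(p$blocks, 1L)
  expect_equal(c(p$min_len, p$max_len), c(5L, 5L))

  msp <- compile_pattern(msp_motif_spec(), name = "msp")
  expect_equal(msp$min_len, 25L)
  expect_equal(msp$max_len, 30L)

  # both spacer spellings compile to the same grammar
  alt <- compile_pattern("CT[AT]TAA[AT]TTN_0-3[AC]AN_0-2TTTTG[CT]CATAA[TA]C[TC]")
  expect_equal(alt$min_len, 25L)
  expect_equal(alt$max_len, 30L)
  # slash-separated choice sets are accepted too
  expect_equal(compile_pattern("CT[A/T]TAA")$min_len, 6L)

  expect_error(compile_pattern("CA[X]CTG"), "\\[X\\]")
  expect_error(compile_pattern("CA[CTG"), "malformed")
  expect_error(compile_pattern("AN(3,1)A"), "malformed")
  expect_error(compile_pattern("N(1,2)ACGT"), "spacer")
  expect_error(compile_pattern("ACGTN"), "spacer")
  expect_error(compile_pattern("AB"), "malformed")

  # bare N is a length-1 spacer; adjacent spacers pool
  p2 <- compile_pattern("ANNA")
  expect_length(p2$blocks, 3L)
  expect_equal(p2$blocks[[2L]]$min, 2L)
  expect_equal(c(p2$min_len, p2$max_len), c(4L, 4L))
})

test_that("match_at anchors exactly and picks the leftmost-shortest spacers", {
  daf3 <- compile_pattern("GTCTA")
  h <- match_at(daf3, "GTCTA", 0)
  expect_equal(h$offset, 0L)
  expect_equal(h$length, 5L)
  expect_null(match_at(daf3, "GTCTA", 1))

  msp <- compile_pattern(msp_motif_spec())
  h1 <- match_at(msp, "CTATAAATTAATTTTGCCATAATCT", 0)
  expect_equal(h1$gap_lengths, c(0L, 0L))
  expect_equal(h1$length, 25L)
  h2 <- match_at(msp, "CTTTAATTTGGGCAGGTTTTGTCATAAACC", 0)
  expect_equal(h2$gap_lengths, c(3L, 2L))
  expect_equal(h2$length, 30L)
  # the brute-force oracle agrees on both derived instances
  for (s in c("CTATAAATTAATTTTGCCATAATCT", "CTTTAATTTGGGCAGGTTTTGTCATAAACC")) {
    o <- oracle_match_at(msp, s, 0)
    expect_equal(match_at(msp, s, 0)[c("length", "gap_lengths")],
                 o[c("length", "gap_lengths")])
  }

  expect_error(match_at(daf3, "ACGT", 9), "out of range")
})

test_that("ambiguity codes in the subject never match, spacers included", {
  pat <- compile_pattern("ANA")
  expect_null(match_at(pat, "ANA", 0))   # N in subject fails even in a spacer
  expect_false(is.null(match_at(pat, "ACA", 0)))
  expect_equal(nrow(scan_region(compile_pattern("GTCTA"),
                                strrep("N", 50))), 0L)
})

test_that("scan_region finds overlapping per-start hits in order", {
  ebox <- compile_pattern("CASCTG")
  h <- scan_region(ebox, "AACAGCTGACACCTGA")
  expect_equal(h$offset, c(2L, 9L))
  expect_equal(nrow(h), 2L)

  # shorter than min_len: empty
  expect_equal(nrow(scan_region(ebox, "CACCT")), 0L)

  # palindromic pattern on both strands: same count each strand
  pal <- compile_pattern("CACGTG")
  h2 <- scan_region(pal, "TTCACGTGTT", both_strands = TRUE)
  expect_equal(sum(h2$strand == "+"), 1L)
  expect_equal(sum(h2$strand == "-"), 1L)

  # overlapping starts are all reported
  h3 <- scan_region(compile_pattern("AA"), "AAAA")
  expect_equal(h3$offset, 0:2)
})

test_that("scan_region equals the exhaustive gap-enumeration oracle", {
  set.seed(42)
  n_cases <- 400L
  for (i in seq_len(n_cases)) {
    spec <- random_pattern_spec()
    p <- compile_pattern(spec)
    s <- random_seq(sample(10:60, 1))
    got <- scan_region(p, s)
    want <- oracle_scan(p, s)
    expect_equal(nrow(got), length(want), info = paste(spec, s))
    if (nrow(got) > 0L) {
      expect_equal(got$offset, vapply(want, `[[`, 1L, "offset"))
      expect_equal(got$length, vapply(want, `[[`, 1L, "length"))
      expect_equal(unname(got$gaps), lapply(want, `[[`, "gap_lengths"),
                   ignore_attr = TRUE)
      # every returned hit re-verifies block-by-block
      for (j in seq_len(nrow(got)))
        expect_true(verify_hit(p, s, got$offset[j], got$gaps[[j]]))
    }
  }
})

test_that("min_len/max_len are tight", {
  set.seed(7)
  for (i in 1:25) {
    p <- compile_pattern(random_pattern_spec())
    # a minimal-length instance matches and spans min_len
    small <- vapply(p$blocks, function(b) switch(b$type,
      lit = b$bases, choice = b$set[1L],
      gap = strrep("A", b$min)), "")
    s_min <- paste(small, collapse = "")
    expect_equal(nchar(s_min), p$min_len)
    expect_equal(match_at(p, s_min, 0)$length, p$min_len)
    # no shorter sequence admits a match
    if (p$min_len > 1L)
      expect_null(match_at(p, substr(s_min, 1L, p$min_len - 1L), 0))
    # a maximal instance anchored at 0 spans the whole sequence
    big <- vapply(p$blocks, function(b) switch(b$type,
      lit = b$bases, choice = b$set[1L],
      gap = strrep("A", b$max)), "")
    s_max <- paste(big, collapse = "")
    expect_equal(nchar(s_max), p$max_len)
    expect_false(is.null(oracle_match_at(p, s_max, 0)))
    # an all-maximal spacer assignment spans the whole sequence
    maxes <- vapply(Filter(function(b) b$type == "gap", p$blocks),
                    `[[`, 1L, "max")
    expect_true(verify_hit(p, s_max, 0L, maxes))
  }
})

test_that("classify_pd_status is the presence-of-both conjunction", {
  set.seed(11)
  cat_ <- motif_catalog()
  daf3_inst <- "GTCTA"
  msp_inst <- "CTATAAATTAATTTTGCCATAATCT"
  spacer <- strrep("T", 20)  # motif-free filler
  regions <- data.frame(
    gene_id = c("both", "daf_only", "neither"),
    seq = c(paste0(daf3_inst, spacer, msp_inst),
            paste0(daf3_inst, strrep("A", 30)),
            strrep("N", 60)))
  st <- classify_pd_status(regions, cat_$daf3, cat_$msp)
  expect_equal(st$has_full_pd, c(TRUE, FALSE, FALSE))
  expect_equal(st$has_daf3, c(TRUE, TRUE, FALSE))
  expect_equal(st$has_conserved, c(TRUE, FALSE, FALSE))
  expect_equal(st$has_full_pd, st$has_daf3 & st$has_conserved)

  expect_error(classify_pd_status(rbind(regions, regions[1L, ])),
               "duplicate")
})

test_that("scan_geneset tallies hits per gene and derives gene sets", {
  regions <- data.frame(
    gene_id = c("g1", "g2"),
    seq = c(paste0("CACCTG", strrep("T", 5), "CAGCTG", strrep("T", 5), "CACCTG"),
            strrep("A", 30)))
  res <- scan_geneset(list(compile_pattern("CASCTG", name = "ebox")), regions)
  expect_equal(res$hits$n_hits, 3L)
  expect_equal(res$sets$ebox, "g1")
  # zero patterns -> empty table
  empty <- scan_geneset(list(), regions)
  expect_equal(nrow(empty$hits), 0L)
})

test_that("motif files round-trip through read_motifs", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# catalog", "daf3\tGTCTA", paste0("msp\t", msp_motif_spec())), f)
  pats <- read_motifs(f)
  expect_named(pats, c("daf3", "msp"))
  expect_equal(pats$msp$max_len, 30L)
  writeLines("justonefield", f)
  expect_error(read_motifs(f), "name pattern")
})
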