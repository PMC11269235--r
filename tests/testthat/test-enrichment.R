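test_that("overlap partitions the union", {
  a <- gene_set("a", c("x", "y", "z"))
  b <- gene_set("b", c("y", "z", "w"))
  expect_equal(overlap(a, b), c(k = 2L, only_a = 1L, only_b = 1L))
  expect_equal(overlap(gene_set("a", c("p", "q")), gene_set("b", "r")),
               c(k = 0L, only_a = 2L, only_b = 1L))
  expect_equal(overlap(a, a), c(k = 3L, only_a = 0L, only_b = 0L))
})

test_that("percentages reproduce printed set arithmetic from printed counts", {
  expect_equal(percent_of_query(3652, 5908, 0), 62)
  expect_equal(percent_of_query(175, 711, 1), 24.6)
  expect_equal(percent_of_query(0, 10, 0), 0)
  expect_error(percent_of_query(0, 0), "positive")

  expect_equal(jaccard_percent(5908, 6001, 5206, 1), 77.7)
  expect_equal(jaccard_percent(6375, 6377, 5951, 1), 87.5)
  expect_equal(jaccard_percent(40, 40, 40, 1), 100.0)
  expect_error(jaccard_percent(0, 0, 0), "union")

  expect_equal(annotate_fraction(33, 101, 1), 32.7)
  expect_equal(annotate_fraction(81, 542, 1), 14.9)
  expect_equal(annotate_fraction(0, 17, 1), 0.0)

  # jaccard is dominated by either query-percentage; ties iff identical
  expect_lte(jaccard_percent(30, 40, 20, 3),
             min(percent_of_query(20, 30, 3), percent_of_query(20, 40, 3)))
})

test_that("log-space hypergeometric tails match exact enumeration", {
  expect_identical(log_hypergeom_sf(0, 5, 5, 10), 0)
  expect_equal(log_hypergeom_sf(5, 5, 5, 10), log10(1 / 252), tolerance = 1e-12)
  expect_equal(10^log_hypergeom_sf(2, 3, 3, 6), 0.5, tolerance = 1e-12)
  expect_error(log_hypergeom_sf(4, 3, 3, 6), "require")
  expect_error(log_hypergeom_sf(2, 3, 3, 2), "require")

  # full grid N <= 12 against exact choose() arithmetic (the acceptance
  # suite runs the N <= 25 grid)
  for (N in 2:12) for (n in 1:N) for (K in 1:N)
    for (k in max(0, n + K - N):min(n, K)) {
      expect_equal(log_hypergeom_sf(k, n, K, N), exact_log10_sf(k, n, K, N),
                   tolerance = 1e-10)
    }
})

test_that("hypergeometric invariants: normalization, monotonicity, symmetry", {
  # pmf sums to 1 in log space at N = 10^4
  N <- 10000L; n <- 2000L; K <- 3000L
  i <- max(0L, n + K - N):min(n, K)
  lp <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lp)
  expect_lt(abs(sum(exp(lp - m)) * exp(m) - 1), 1e-12)

  # non-increasing in k; symmetric in (n, K)
  for (k in 0:20) {
    if (k > 0)
      expect_lte(log_hypergeom_sf(k, 20, 30, 100),
                 log_hypergeom_sf(k - 1, 20, 30, 100))
    expect_equal(log_hypergeom_sf(k, 20, 30, 100),
                 log_hypergeom_sf(k, 30, 20, 100), tolerance = 1e-10)
  }

  # extreme tail stays finite and matches elementary log arithmetic
  lt <- log_hypergeom_sf(4000, 4000, 10000, 20000)
  expect_true(is.finite(lt))
  expect_lt(lt, -1200)
  expect_equal(lt, extreme_tail_log10(4000, 10000, 20000), tolerance = 1e-6)

  # and the lower tail mirrors phyper's log-space result
  expect_equal(log_hypergeom_cdf(5, 50, 40, 200) * log(10),
               stats::phyper(5, 40, 160, 50, log.p = TRUE), tolerance = 1e-10)
  expect_equal(log_hypergeom_sf(30, 50, 40, 200) * log(10),
               stats::phyper(29, 40, 160, 50, lower.tail = FALSE, log.p = TRUE),
               tolerance = 1e-10)
})

test_that("enrichment_test assembles the 2x2 and applies the tail conventions", {
  pop <- gene_set("pop", sprintf("g%03d", 1:100))
  q <- gene_set("q", sprintf("g%03d", 1:20))
  r <- gene_set("r", sprintf("g%03d", 11:40))
  res <- enrichment_test(q, r, pop)
  expect_equal(res$k, 10L)
  expect_equal(res$expected, 20 * 30 / 100)
  expect_equal(res$direction, "enriched")
  expect_equal(res$fold, 10 / 6)
  expect_equal(res$log10_p, log_hypergeom_sf(10, 20, 30, 100))

  # reference = population saturates: fold 1, p = 1
  sat <- enrichment_test(q, pop, pop)
  expect_equal(sat$fold, 1)
  expect_identical(sat$log10_p, 0)

  # k exactly expected counts as enriched with fold 1
  q2 <- gene_set("q2", sprintf("g%03d", 1:10))
  r2 <- gene_set("r2", sprintf("g%03d", c(1, 11:19)))
  res2 <- enrichment_test(q2, r2, pop)  # expected 10*10/100 = 1, k = 1
  expect_equal(res2$direction, "enriched")
  expect_equal(res2$fold, 1)

  # depletion uses the lower tail and the under-enrichment fold
  qd <- gene_set("qd", sprintf("g%03d", 1:50))
  rd <- gene_set("rd", sprintf("g%03d", c(1, 51:90)))
  resd <- enrichment_test(qd, rd, pop)  # expected 20.5, observed 1
  expect_equal(resd$direction, "depleted")
  expect_equal(resd$fold, (50 * 41 / 100) / 1)
  expect_equal(resd$log10_p, log_hypergeom_cdf(1, 50, 41, 100))

  expect_error(enrichment_test(gene_set("q", "zzz"), r, pop), "zzz")
})

test_that("p_display renders from log10_p without exponentiating", {
  expect_equal(p_display(log10(5.5e-13)), "5.5e-13")
  expect_equal(p_display(-1160.0110), "9.7e-1161")
  expect_equal(p_display(0), "1")
  expect_equal(p_display(-513.8996), "1.3e-514")
})

test_that("dependence partition reproduces the wild-type-only arithmetic", {
  ids <- sprintf("d%04d", 1:1500)
  wt_up <- gene_set("wt_up", ids[1:116])
  mut_up <- gene_set("mut_up", c(ids[1:15], ids[801:881]))      # 15 shared, 96 total
  wt_down <- gene_set("wt_down", ids[117:711])                  # 595 genes
  mut_down <- gene_set("mut_down", c(ids[117:169], ids[901:952]))  # 53 shared, 105 total
  part <- dependence_partition(wt_up, wt_down, mut_up, mut_down)
  expect_equal(length(part$dependent_up$members), 101L)
  expect_equal(length(part$dependent_down$members), 542L)
  expect_equal(part$shared_up, 15L)
  expect_equal(part$shared_down, 53L)
  expect_equal(part$percent_dependent, 90)

  # pure set algebra: invariant under member relabeling
  relabel <- function(s) gene_set(s$name, paste0("X", s$members))
  part2 <- dependence_partition(relabel(wt_up), relabel(wt_down),
                                relabel(mut_up), relabel(mut_down))
  expect_equal(part2$percent_dependent, part$percent_dependent)
  expect_equal(length(part2$dependent_down$members),
               length(part$dependent_down$members))

  expect_error(dependence_partition(wt_up, wt_up, mut_up, mut_down),
               "overlap")
})

test_that("gene lists round-trip through the plain-text dialect", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "g1", "g2", "", "g2  # dup and trailing comment"), f)
  s <- read_gene_list(f, name = "listy")
  expect_equal(s$members, c("g1", "g2"))
  write_gene_list(s, f)
  expect_equal(read_gene_list(f)$members, c("g1", "g2"))
})
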