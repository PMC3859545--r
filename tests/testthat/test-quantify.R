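test_that("union counting assigns unique hits and sets aside the rest", {
  ann <- toy_overlap_annotation()
  reads <- rbind(
    do.call(rbind, lapply(0:9, function(i) read_row("1", 1099 + i))),  # G1 only
    read_row("1", 1700),   # overlap of G1 and G2 -> ambiguous
    read_row("1", 100),    # outside every gene
    read_row("2", 5499))   # G3 (unstranded here)
  cm <- count_reads(reads, ann, stranded = FALSE)
  expect_equal(unname(cm$counts["G1", "S"]), 10L)
  expect_equal(unname(cm$counts["G2", "S"]), 0L)
  expect_equal(unname(cm$counts["G3", "S"]), 1L)
  expect_equal(unname(cm$ambiguous["S"]), 1L)
  expect_equal(unname(cm$no_feature["S"]), 1L)
  expect_equal(sum(cm$counts[, "S"]) + cm$ambiguous[["S"]] +
                 cm$no_feature[["S"]], nrow(reads))

  # strand-aware counting drops the antisense read (G3 is on "-")
  cm2 <- count_reads(read_row("2", 5499, strand = "+"), ann, stranded = TRUE)
  expect_equal(unname(cm2$counts["G3", "S"]), 0L)
  expect_equal(unname(cm2$no_feature[["S"]]), 1L)

  expect_error(count_reads(read_row("chrUn", 5), ann), "chrUn")
})

test_that("counting conservation holds on random read sets", {
  ann <- toy_overlap_annotation()
  withr::with_seed(3, {
    for (i in 1:3) {
      n <- 500
      reads <- data.frame(
        contig = sample(c("1", "2"), n, replace = TRUE),
        start = sample(0:7000, n, replace = TRUE),
        strand = sample(c("+", "-"), n, replace = TRUE),
        sample_id = sample(c("A", "B"), n, replace = TRUE),
        stringsAsFactors = FALSE)
      cm <- count_reads(reads, ann, stranded = FALSE)
      expect_equal(colSums(cm$counts) + cm$ambiguous + cm$no_feature,
                   cm$lib_size)
      expect_equal(sum(cm$lib_size), n)
    }
  })
})

test_that("contig distribution tallies reads and the MT share", {
  reads <- rbind(read_row("MT", 10), read_row("MT", 20), read_row("1", 30),
                 read_row("1", 40, sample = "B"))
  cd <- contig_distribution(reads)
  expect_equal(unname(cd$counts["MT", "S"]), 2L)
  expect_equal(unname(cd$mt_share[["S"]]), 2 / 3)
  expect_equal(unname(cd$totals[["B"]]), 1L)
  empty <- contig_distribution(read_row("1", 1)[0, ])
  expect_equal(length(empty$totals), 0)
})

test_that("FPKM follows the defining formula and inverts exactly", {
  m <- matrix(c(500L, 0L), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  f <- compute_fpkm(m, c(g1 = 1000, g2 = 500), lib_size = 1e6)
  expect_equal(unname(f["g1", 1]), 500.0)
  expect_equal(unname(f["g2", 1]), 0.0)
  expect_equal(compute_fpkm(m, c(g1 = 1000, g2 = 500), lib_size = 2e6)["g1", 1],
               f["g1", 1] / 2, ignore_attr = TRUE)

  withr::with_seed(7, {
    cnt <- matrix(rpois(60, 50), 20, 3,
                  dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
    L <- setNames(sample(200:5000, 20), rownames(cnt))
    N <- colSums(cnt)
    fp <- compute_fpkm(cnt, L, N)
    back <- fp * outer(L[rownames(cnt)], N) / 1e9
    expect_equal(back, cnt * 1.0, tolerance = 1e-9, ignore_attr = TRUE)
  })
  expect_error(compute_fpkm(m, c(g1 = 0, g2 = 500), lib_size = 1e6), "lengths")
  expect_error(compute_fpkm(m, c(g1 = 1000, g2 = 500), lib_size = 0), "library")
})

test_that("NRC applies the decay-length correction", {
  m <- matrix(1000L, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(unname(compute_nrc(m, c(g1 = 673))[1, 1]), 1155.7,
               tolerance = 1e-4)
  expect_equal(unname(compute_nrc(m, c(g1 = 1e7))[1, 1]), 1000.0)
  # NRC/count falls monotonically with length
  Ls <- c(g1 = 100, g2 = 500, g3 = 2000, g4 = 10000)
  mm <- matrix(1000L, 4, 1, dimnames = list(names(Ls), "s1"))
  ratios <- compute_nrc(mm, Ls)[, 1] / 1000
  expect_true(all(diff(ratios) < 0))
  # paper and exact modes agree for long transcripts
  long <- matrix(1000L, 1, 1, dimnames = list("g1", "s1"))
  Ll <- c(g1 = 3 / 0.0027638)
  expect_lt(abs(compute_nrc(long, Ll, mode = "paper")[1, 1] -
                compute_nrc(long, Ll, mode = "exact")[1, 1]) /
              compute_nrc(long, Ll, mode = "exact")[1, 1], 0.003)
  expect_error(compute_nrc(m, c(gX = 673)), "g1")
})

test_that("protocol adjustment makes matched libraries comparable", {
  # one gene at the same molar abundance in both protocols, L = 5000:
  # raw counts differ hugely, adjusted values agree within 2x
  lam <- 0.0027638
  L <- c(gA = 5000, gB = 400)
  abund <- c(gA = 1, gB = 1)
  polya <- round(1e4 * abund * (1 - exp(-lam * L)))
  tot <- round(1e4 * abund * L / 1000)
  m <- cbind(S0 = polya, S1 = tot)
  prot <- c(S0 = "polyA+", S1 = "totRNA")
  adj <- protocol_adjust(m, L, lam, protocol = prot)
  expect_equal(adj[, "S0"],
               round(compute_nrc(m[, 1, drop = FALSE], L, lam))[, 1],
               ignore_attr = TRUE)
  # size-factor-style rescale: compare gene ratios across protocols
  rel_adj <- (adj[, "S0"] / sum(adj[, "S0"])) / (adj[, "S1"] / sum(adj[, "S1"]))
  rel_raw <- (m[, "S0"] / sum(m[, "S0"])) / (m[, "S1"] / sum(m[, "S1"]))
  expect_true(all(rel_adj < 2 & rel_adj > 0.5))
  expect_gt(max(rel_raw, 1 / rel_raw), 2)

  expect_error(protocol_adjust(m, L, lam, protocol = c(S0 = "polyA+")),
               "protocol")
})

test_that("ranking sorts, breaks ties by gene id and can drop MT genes", {
  m <- matrix(c(5, 9, 9, 1), 4, 1,
              dimnames = list(c("gD", "gC", "gA", "gM"), "s1"))
  rt <- rank_table(m, 4)
  expect_equal(rt$gene_id, c("gA", "gC", "gD", "gM"))
  expect_equal(rank_table(m, 1)$gene_id, "gA")
  contig <- c(gD = "1", gC = "2", gA = "3", gM = "MT")
  expect_false("gM" %in% rank_table(m, 4, contig = contig,
                                    exclude_mt = TRUE)$gene_id)
  expect_error(rank_table(m, 0), "top_n")
})

test_that("expression correlation filters to genes detected in both inputs", {
  a <- c(g1 = 1, g2 = 2, g3 = 3)
  expect_equal(as.numeric(correlate_expression(a, a, "pearson")), 1.0)
  expect_equal(as.numeric(correlate_expression(a, a, "spearman")), 1.0)
  expect_equal(as.numeric(correlate_expression(a, 2 * a, "pearson")), 1.0)
  b <- c(g1 = 3, g2 = 1, g3 = 2)
  expect_equal(as.numeric(correlate_expression(a, b, "spearman")), -0.5)
  expect_equal(attr(correlate_expression(a, b, "pearson"), "n"), 3L)
  expect_error(correlate_expression(c(g1 = 1, g2 = 0, g3 = 0),
                                    c(g1 = 1, g2 = 1, g3 = 1), "pearson"),
               "3 shared")
})
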