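test_that("annotation generation is deterministic and structurally complete", {
  cfg <- simulation_config(n_genes = 50, seed = 1)
  ann1 <- generate_annotation(cfg)
  ann2 <- generate_annotation(cfg)
  p1 <- tempfile(fileext = ".gtf"); p2 <- tempfile(fileext = ".gtf")
  write_gtf(ann1, p1); write_gtf(ann2, p2)
  expect_identical(readLines(p1), readLines(p2))

  gt <- gene_table(ann1)
  expect_true(sum(gt$mitochondrial) >= 1)
  expect_true(any(gt$contig == "Y"))
  two <- ann1$transcripts[["PPBP.t1"]]
  expect_equal(two$polya_sites, c(708, 1307))

  # custom two-site placement is honored
  ann3 <- generate_annotation(simulation_config(n_genes = 50, seed = 1),
                              two_site_positions = c(500, 900),
                              two_site_weights = c(0.7, 0.3))
  expect_equal(ann3$transcripts[["PPBP.t1"]]$polya_sites, c(500, 900))
  expect_equal(ann3$transcripts[["PPBP.t1"]]$site_weights, c(0.7, 0.3))
})

test_that("invalid configuration is rejected with the field name", {
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(simulation_config(lam = -1), "lam")
  expect_error(simulation_config(mt_fraction = 1.2), "mt_fraction")
  expect_error(simulation_config(dispersion = -0.1), "dispersion")
  # too few genes to hold the structured set
  expect_error(generate_annotation(simulation_config(n_genes = 3)), "n_genes")
})

test_that("written GTF is standard-compliant (round trip through rtracklayer)", {
  ann <- generate_annotation(simulation_config(n_genes = 46, seed = 3))
  path <- tempfile(fileext = ".gtf")
  write_gtf(ann, path)
  gr <- rtracklayer::import(path, format = "gtf")
  exons <- gr[gr$type == "exon"]
  expect_equal(length(exons), length(ann$transcripts))
  gt <- gene_table(ann)
  idx <- match(exons$transcript_id, names(ann$transcripts))
  expect_false(anyNA(idx))
  expect_equal(GenomicRanges::start(exons),
               unname(vapply(ann$transcripts[idx], `[[`, integer(1),
                             "tx_start")))
  expect_equal(GenomicRanges::end(exons),
               unname(vapply(ann$transcripts[idx], `[[`, integer(1),
                             "tx_end")))
})

test_that("polyA+ profile draws exact totals from the decay mixture", {
  tx <- toy_transcript(L = 2000)
  expect_equal(sum(simulate_polya_profile(tx, 0, seed = 1)$values), 0)
  prof <- simulate_polya_profile(tx, 200000, lam = 0.0027638, seed = 5)
  expect_equal(sum(prof$values), 200000)
  expect_true(all(prof$values[seq_len(tx$leader_len)] == 0))

  # refit recovers the generating rate within 3 SE
  fit <- fit_decay(prof)
  expect_lt(abs(fit$lam - 0.0027638), 3 * fit$stderr)

  # a transcript stripped of its sites is unusable
  broken <- tx; broken$polya_sites <- numeric(0)
  expect_error(simulate_polya_profile(broken, 10), "polyA")
})

test_that("mean refit slope over 20 seeds is within 1% of the generating rate", {
  tx <- toy_transcript(L = 2000)
  lams <- vapply(1:20, function(s)
    fit_decay(simulate_polya_profile(tx, 200000, 0.0027638, seed = s))$lam,
    numeric(1))
  expect_lt(abs(mean(lams) - 0.0027638) / 0.0027638, 0.01)
})

test_that("two-site profiles split reads according to site usage", {
  tx <- toy_transcript(L = 1307, sites = c(708, 1307),
                       weights = c(100, 1) / 101)
  prof <- simulate_polya_profile(tx, 200000, lam = 0.0027638, seed = 9)
  expect_equal(sum(prof$values), 200000)
  # decay-corrected weights recover the ~100:1 usage ratio
  w <- isoform_abundance_ratio(prof, c(708, 1307), 0.0027638, leader_len = 30)
  expect_lt(abs(w[1] / w[2] - 100) / 100, 0.2)
})

test_that("uniform profiles are flat: binomial bins and null decay fit", {
  tx <- toy_transcript(L = 1000)
  expect_equal(sum(simulate_uniform_profile(tx, 0)$values), 0)
  expect_error(simulate_uniform_profile(tx, -5), "n_reads")
  prof <- simulate_uniform_profile(tx, 100000, seed = 2)
  expect_equal(sum(prof$values), 100000)
  bins <- bin_coverage(prof, 100)$values
  sigma <- sqrt(100000 * 0.1 * 0.9)
  expect_true(all(abs(bins - 10000) <= 4 * sigma))

  pvals <- vapply(1:20, function(s)
    fit_decay(simulate_uniform_profile(toy_transcript(L = 2000), 100000,
                                       seed = s))$p_value, numeric(1))
  expect_gte(sum(pvals > 0.01), 18)
})

test_that("read-start simulation respects MT share, determinism and empty libraries", {
  cfg <- simulation_config(n_genes = 50, library_size = 1e5,
                           mt_fraction = 0.63, seed = 4)
  ann <- generate_annotation(cfg)
  reads <- simulate_read_starts(ann, cfg)
  s0 <- reads[reads$sample_id == "S0", ]
  share <- mean(s0$contig == "MT")
  sigma <- sqrt(0.63 * 0.37 / nrow(s0))
  expect_lt(abs(share - 0.63), 3 * sigma)

  # female sample has no Y-contig reads; totRNA reads are strand-specific
  gt <- gene_table(ann)
  s2 <- reads[reads$sample_id == "S2", ]
  expect_equal(sum(s2$contig == "Y"), 0)
  ppbp <- reads[reads$sample_id == "S1" & reads$contig == "4", ]
  expect_true(all(ppbp$strand == "+"))

  reads2 <- simulate_read_starts(ann, cfg)
  p1 <- tempfile(fileext = ".bed"); p2 <- tempfile(fileext = ".bed")
  write_read_bed(reads, p1); write_read_bed(reads2, p2)
  expect_identical(readLines(p1), readLines(p2))

  cfg0 <- simulation_config(n_genes = 50, library_size = 0, seed = 4)
  empty <- simulate_read_starts(ann, cfg0)
  p0 <- tempfile(fileext = ".bed")
  write_read_bed(empty, p0)
  expect_equal(length(readLines(p0)), 1L)  # header only

  bad_design <- default_design()
  bad_design$protocol[2] <- "ribo-zero"
  expect_error(simulate_read_starts(ann, cfg, bad_design), "protocol")
})

test_that("count simulation is NB with Poisson limit and seeded determinism", {
  des <- data.frame(sample_id = sprintf("r%04d", 1:5000),
                    group = rep("A", 5000))
  cfg <- simulation_config(seed = 8, library_size = 800, dispersion = 0)
  cnt <- simulate_counts(NULL, des, cfg, mu = c(g1 = 1))
  ratio <- var(as.numeric(cnt)) / mean(cnt)
  expect_gt(ratio, 0.9); expect_lt(ratio, 1.1)

  des6 <- data.frame(sample_id = paste0("r", 1:6), group = rep(c("A", "B"), 3))
  cfg2 <- simulation_config(seed = 9, library_size = 1e4, dispersion = 0.1)
  mu <- setNames(rep(1, 50), paste0("g", 1:50))
  c1 <- simulate_counts(NULL, des6, cfg2, mu = mu)
  c2 <- simulate_counts(NULL, des6, cfg2, mu = mu)
  expect_identical(c1, c2)

  expect_error(simulate_counts(NULL, des6, cfg2, mu = c(g1 = -2)), "negative")
  expect_error(simulate_counts(NULL, des6[1, , drop = FALSE], cfg2,
                               mu = mu), "2 samples")
})
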