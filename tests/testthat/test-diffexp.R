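test_that("median-of-ratios size factors match the closed forms", {
  m <- matrix(c(10, 20, 30, 10, 20, 30), 3, 2,
              dimnames = list(paste0("g", 1:3), c("a", "b")))
  expect_equal(unname(size_factors(m)), c(1, 1))

  m2 <- m; m2[, "b"] <- 2 * m2[, "a"]
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))

  perm <- m2[c(3, 1, 2), ]
  expect_equal(size_factors(perm), size_factors(m2))

  mz <- m; mz[, 1] <- 0
  expect_error(size_factors(mz), "nonzero")
})

test_that("dispersion estimation recovers Poisson and NB regimes", {
  des <- data.frame(sample_id = paste0("r", 1:6),
                    group = rep(c("A", "B"), each = 3))
  # Poisson limit
  cfg <- simulation_config(seed = 31, library_size = 3e4, dispersion = 0)
  mu <- setNames(exp(runif(50, log(20), log(1000))), paste0("g", 1:50))
  cnt <- simulate_counts(NULL, des, cfg, mu = mu)
  sf <- size_factors(cnt)
  disp <- estimate_dispersions(cnt, sf, des$group)
  expect_lte(median(disp$alpha_final), 0.05)

  # moment recovery at alpha = 0.2, mu = 1000
  raws <- vapply(1:10, function(s) {
    cfg2 <- simulation_config(seed = 600 + s, library_size = 2e5,
                              dispersion = 0.2)
    mu2 <- setNames(rep(1, 200), paste0("g", 1:200))  # -> mean 1000 each
    cnt2 <- simulate_counts(NULL, des, cfg2, mu = mu2)
    d <- estimate_dispersions(cnt2, size_factors(cnt2), des$group)
    mean(d$alpha_raw)
  }, numeric(1))
  expect_gt(mean(raws), 0.15); expect_lt(mean(raws), 0.25)

  # hyperbolic curve falls with mu when a1 > 0
  if (disp$a1 > 0) {
    grid <- disp$a0 + disp$a1 / c(10, 100, 1000)
    expect_true(all(diff(grid) < 0))
  }
  expect_error(estimate_dispersions(cnt[, 1:2], sf[1:2], c("A", "B")),
               "usable")
})

test_that("fold-change conventions handle zeros the way the DE tables print them", {
  expect_equal(fold_change(2, 10), 5)
  expect_equal(fold_change(2, 0), 0)
  expect_equal(fold_change(0, 2), Inf)
  expect_true(is.nan(fold_change(0, 0)))
  expect_equal(log2(fold_change(2, 0)), -Inf)
})

test_that("the NB exact-style test is deterministic and flags empty genes", {
  des <- data.frame(sample_id = paste0("r", 1:6),
                    group = rep(c("A", "B"), each = 3))
  cfg <- simulation_config(seed = 33, library_size = 5e4, dispersion = 0.05)
  mu <- setNames(exp(runif(40, log(20), log(1000))), paste0("g", 1:40))
  cnt <- simulate_counts(NULL, des, cfg, mu = mu)
  cnt["g1", ] <- 0L
  sf <- size_factors(cnt)
  disp <- estimate_dispersions(cnt, sf, des$group)
  r1 <- nb_test(cnt, sf, disp, des$group)
  r2 <- nb_test(cnt, sf, disp, des$group)
  expect_identical(r1, r2)
  expect_true(all(r1$pval >= 0 & r1$pval <= 1))
  expect_true(all(r1$padj >= r1$pval))
  g1 <- r1[r1$gene_id == "g1", ]
  expect_equal(g1$pval, 1)
  expect_true(is.nan(g1$FC))
  expect_true(g1$zero_total)
  expect_equal(r1$baseMean,
               (3 * r1$baseMeanA + 3 * r1$baseMeanB) / 6, tolerance = 1e-12)
})

test_that("a strongly depleted gene is reported with a large negative log2FC", {
  # 2 vs 1 contrast with group means emulating a Y-linked gene in a female
  # sample: ~2266 in males, ~3.5 in the female
  des <- data.frame(sample_id = c("S1", "S3", "S2"), group = c("M", "M", "F"))
  cfg <- simulation_config(seed = 35, library_size = 100 * 2265.7,
                           dispersion = 0,
                           fold_changes = list(F = c(gY = 3.5 / 2265.7)))
  mu <- setNames(rep(1, 100), c("gY", paste0("g", 1:99)))
  cnt <- simulate_counts(NULL, des, cfg, mu = mu)
  sf <- size_factors(cnt)
  disp <- estimate_dispersions(cnt, sf, des$group)
  res <- nb_test(cnt, sf, disp, factor(des$group, levels = c("M", "F")))
  row <- res[res$gene_id == "gY", ]
  expect_lte(row$log2FC, -7.5)
  expect_lt(row$padj, 0.10)
})

test_that("BH adjustment reproduces the hand step-up and caps at 1", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  withr::with_seed(11, {
    p <- runif(15)
    expect_true(all(bh_adjust(p) >= p))
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  expect_error(bh_adjust(c(0.5, NA)), "0, 1")
})

test_that("FDR filtering sorts by adjusted p-value", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    padj = c(0.5, 0.01, 0.09))
  expect_equal(de_genes(res, 0.10)$gene_id, c("b", "c"))
  expect_equal(nrow(de_genes(res[0, ], 0.10)), 0)
  expect_equal(nrow(de_genes(res, 1.0)), 3)
})

test_that("BCV summary reports sqrt-dispersion against CPM", {
  des <- data.frame(sample_id = paste0("r", 1:6),
                    group = rep(c("A", "B"), each = 3))
  cfg <- simulation_config(seed = 37, library_size = 1e5, dispersion = 1)
  mu <- setNames(exp(seq(log(5), log(5000), length.out = 60)),
                 paste0("g", 1:60))
  alpha <- setNames(0.02 + 20 / (mu / sum(mu) * 1e5), names(mu))
  cfg$dispersion <- alpha
  cnt <- simulate_counts(NULL, des, cfg, mu = mu)
  sf <- size_factors(cnt)
  disp <- estimate_dispersions(cnt, sf, des$group)
  expect_equal(disp$bcv, sqrt(disp$alpha_final))
  tab <- bcv_summary(disp, cnt, sf)
  # a count of 100 in a library of 1e6 is 100 CPM
  one <- matrix(c(100L, 999900L), 2, 1, dimnames = list(c("g", "rest"), "s"))
  d0 <- list(bcv = c(0.2, 0.2), alpha_final = c(0.04, 0.04))
  class(d0) <- "dispersion_estimate"
  t0 <- bcv_summary(d0, one, c(s = 1))
  expect_equal(t0$cpm[1], 100)
  expect_equal(t0$bcv[1], 0.2)
  # expression-dependent noise: high-CPM genes have lower BCV
  hi <- tab$bcv[tab$cpm > median(tab$cpm)]
  lo <- tab$bcv[tab$cpm <= median(tab$cpm)]
  expect_lt(median(hi), median(lo))
})
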