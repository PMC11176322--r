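flat <- function(cn, n_bins = 100) rep(as.integer(cn), n_bins)

test_that("normal-diploid and G2-like cells are excluded, aberrant cells kept", {
  cn <- cbind(dip = flat(2),
              g2 = c(flat(4, 96), flat(2, 4)),      # 96% CN 4
              tumor = c(flat(3, 20), flat(2, 80)))  # 20% altered
  res <- filter_normal_cells(cn)
  expect_equal(colnames(res$retained), "tumor")
  expect_equal(res$excluded$reason[res$excluded$cell_id == "dip"],
               "normal_diploid")
  expect_equal(res$excluded$reason[res$excluded$cell_id == "g2"],
               "g2_tetraploid")
  # idempotent
  res2 <- filter_normal_cells(res$retained)
  expect_equal(res2$retained, res$retained)
})

test_that("noisy cells are those sharing under a third of their features", {
  chrom <- rep(c("chr1", "chr2"), each = 50)
  base <- flat(2)
  aberr <- base; aberr[10:30] <- 3L
  noisy <- base; noisy[c(5:8, 40:44, 60:71, 80:93)] <- c(1L)
  cn <- cbind(a = aberr, b = aberr, weird = noisy)
  res <- filter_noisy_cells(cn, chrom)
  expect_equal(colnames(res$retained), c("a", "b"))
  expect_equal(res$excluded$cell_id, "weird")
  expect_equal(unname(res$share[c("a", "b")]), c(1, 1))

  # a cell sharing half its breakpoints survives the 33% rule
  half <- aberr; half[60:75] <- 3L  # two shared bps + two private
  res2 <- filter_noisy_cells(cbind(a = aberr, b = aberr, c = half), chrom)
  expect_true("c" %in% colnames(res2$retained))
  expect_equal(unname(res2$share["c"]), 0.5)

  # a breakpoint-free cell is retained; its aberrant partner, whose
  # breakpoints nobody else shares, is not
  res3 <- filter_noisy_cells(cbind(a = aberr, b = base), chrom)
  expect_equal(colnames(res3$retained), "b")
  expect_warning(filter_noisy_cells(cbind(a = aberr), chrom), "no-op")
})

test_that("whole-chromosome aberrations count as shareable features", {
  chrom <- rep(c("chr1", "chr2"), each = 50)
  wc <- c(flat(3, 50), flat(2, 50))  # chr1 uniformly gained, no breakpoint
  res <- filter_noisy_cells(cbind(a = wc, b = wc, c = flat(2)), chrom)
  expect_equal(ncol(res$retained), 3)
  expect_equal(unname(res$share[c("a", "b")]), c(1, 1))
})

test_that("pairwise diversity is the fraction of differing bins and a pseudometric", {
  a <- flat(2); b <- flat(2); b[1:50] <- 3L; c <- flat(3)
  res <- pairwise_diversity(cbind(a = a, b = b, c = c))
  expect_equal(res$matrix["a", "b"], 0.5)
  expect_equal(res$matrix["a", "a"], 0)
  expect_equal(res$matrix, t(res$matrix))
  # bin-wise triangle inequality
  expect_lte(res$matrix["a", "c"],
             res$matrix["a", "b"] + res$matrix["b", "c"])
  # ploidy-group restriction drops cross-group pairs
  resg <- pairwise_diversity(cbind(a = a, b = b, c = c),
                             ploidy_group = c("3N", "3N", "6N"))
  expect_true(is.na(resg$matrix["a", "c"]))
  expect_equal(resg$mean_diversity, 0.5)
})

test_that("Shannon evenness matches hand-computed clone proportions", {
  # two clones at 50/50: maximal evenness
  cn <- cbind(a = flat(2), b = flat(2), c = flat(3), d = flat(3))
  expect_equal(shannon_evenness(cn)$evenness, 1)
  # single clone: defined as 0
  expect_equal(shannon_evenness(cbind(a = flat(2), b = flat(2)))$evenness, 0)
  # proportions (0.9, 0.1): H = 0.325, evenness = H / ln 2 = 0.469
  cells <- cbind(matrix(flat(2), 100, 9), flat(3))
  ev <- shannon_evenness(cells)
  expect_equal(ev$n_clones, 2)
  expect_equal(ev$evenness, 0.469, tolerance = 1e-3)
  # smoothing absorbs an isolated single-bin difference
  jitter <- cbind(a = flat(2), b = replace(flat(2), 50, 3L))
  expect_equal(shannon_evenness(jitter)$n_clones, 1)
  expect_equal(shannon_evenness(jitter, smooth = FALSE)$n_clones, 2)
})

test_that("wGII weights chromosomes equally and skips masked ones", {
  chrom <- rep(paste0("chr", 1:4), each = 25)
  prof <- flat(2)
  expect_equal(wgii(prof, chrom, ploidy = 2), 0)
  expect_equal(wgii(flat(5), chrom, ploidy = 2), 1)
  # exactly one of four chromosomes fully deviant -> 1/4
  prof[1:25] <- 3L
  expect_equal(wgii(prof, chrom, ploidy = 2), 0.25)
  # length-independence: the same single deviant chromosome, uneven sizes
  chrom_uneven <- rep(paste0("chr", 1:4), times = c(70, 10, 10, 10))
  prof2 <- flat(2); prof2[1:70] <- 3L
  expect_equal(wgii(prof2, chrom_uneven, ploidy = 2), 0.25)
  # masked chromosome drops out of the mean
  prof3 <- flat(2); prof3[1:25] <- NA
  prof3[26:50] <- 3L
  expect_equal(wgii(prof3, chrom, ploidy = 2), 1 / 3)
  # invariance under relabeling
  expect_equal(wgii(prof, rev(chrom), ploidy = 2),
               wgii(prof, chrom, ploidy = 2))
})

test_that("ploidy is the mean copy number and WGD flags at the threshold", {
  expect_equal(ploidy_and_wgd(flat(2)), list(ploidy = 2, wgd = FALSE))
  half <- c(flat(2, 50), flat(4, 50))
  expect_equal(ploidy_and_wgd(half), list(ploidy = 3, wgd = TRUE))
  expect_true(ploidy_and_wgd(flat(6))$wgd)
})

test_that("diversity increases with divergence and planted outliers are filtered", {
  founder <- random_founder_profile(sim_config(seed = 61, n_bins = 600,
                                               n_chromosomes = 6))
  mean_div <- vapply(c(0.01, 0.05, 0.15), function(rate) {
    cfg <- sim_config(seed = 62, n_bins = 600, n_chromosomes = 6)
    sim <- generate_single_cell_tumor(cfg, n_cells = 30, founder = founder,
                                      divergence_rate = rate)
    pairwise_diversity(sim$cn)$mean_diversity
  }, 0)
  expect_true(all(diff(mean_div) > 0))

  cfg <- sim_config(seed = 63, n_bins = 3000, n_chromosomes = 20)
  founder20 <- random_founder_profile(cfg)
  sim <- generate_single_cell_tumor(cfg, n_cells = 80, founder = founder20,
                                    divergence_rate = 0.05,
                                    contaminant_fraction = 0.15,
                                    noisy_fraction = 0.05)
  res1 <- filter_normal_cells(sim$cn)
  res2 <- filter_noisy_cells(res1$retained, cfg$chrom)
  excluded <- c(res1$excluded$cell_id, res2$excluded$cell_id)
  planted <- sim$truth$cell_id[sim$truth$label != "tumor"]
  sens <- mean(planted %in% excluded)
  expect_gte(sens, 0.95)
  kept_tumor <- setdiff(colnames(res2$retained), planted)
  expect_gte(length(kept_tumor) / sum(sim$truth$label == "tumor"), 0.9)
})

test_that("group comparison wraps the rank-sum test symmetrically", {
  set.seed(5)
  vals <- c(rnorm(20, 0.1, 0.02), rnorm(20, 0.3, 0.02))
  grp <- rep(c("E", "EP"), each = 20)
  res <- group_compare(vals, grp)
  expect_lt(res$tests$E_vs_EP$p_value, 0.05)
  res_swapped <- group_compare(vals, rep(c("EP", "E"), each = 20))
  expect_equal(res_swapped$tests$EP_vs_E$p_value, res$tests$E_vs_EP$p_value)
  expect_equal(group_compare(c(1, 2, 3, 1, 2, 3),
                             rep(c("a", "b"), each = 3))$tests$a_vs_b$p_value, 1)
})
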