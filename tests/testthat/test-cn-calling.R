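mini_track <- function(ratio, chrom = rep("chr1", length(ratio)),
                       masked = rep(FALSE, length(ratio))) {
  structure(data.frame(chrom = chrom,
                       start = (seq_along(ratio) - 1) * 1e6,
                       end = seq_along(ratio) * 1e6,
                       ratio = ifelse(masked, NA_real_, ratio),
                       masked = masked, stringsAsFactors = FALSE),
            class = c("depth_ratio_track", "data.frame"))
}

test_that("depth ratios are library-size normalized and mask zero-coverage bins", {
  grid <- data.frame(chrom = "chr1", start = 0:4 * 1e6, end = 1:5 * 1e6)
  p <- cbind(grid, count = c(100L, 120L, 0L, 90L, 110L))
  d <- cbind(grid, count = c(100L, 120L, 50L, 90L, 110L))
  tr <- compute_depth_ratio(p, p)
  expect_true(all(tr$ratio[!tr$masked] == 1))
  tr2 <- compute_depth_ratio(p, d)
  expect_true(tr2$masked[3])
  expect_true(is.na(tr2$ratio[3]))

  # doubling the daughter library changes nothing
  d2 <- d; d2$count <- d$count * 2L
  expect_equal(compute_depth_ratio(p, d2)$ratio, tr2$ratio)

  bad <- d; bad$start[2] <- 99
  expect_error(compute_depth_ratio(p, bad), "discrepancy at row 2")
})

test_that("planted coverage doubling is recovered in the ratio track", {
  cfg <- sim_config(seed = 19, n_bins = 1000, n_chromosomes = 10)
  ev <- planted_events("chr2", 101, 200, "gain", 2, cfg)  # 10% of bins, x2
  pair <- generate_clone_pair(cfg, ploidy = 2, events = ev, mean_depth = 300)
  tr <- compute_depth_ratio(pair$progenitor, pair$daughter)
  scaling <- sum(pair$progenitor$count) / sum(pair$daughter$count)
  expect_equal(mean(tr$ratio[101:200]), 2 * scaling, tolerance = 0.05)
})

test_that("SNP balance testing applies the depth/alt filters and the exact binomial", {
  snps <- data.frame(chrom = "chr1", pos = c(1e5, 2e5, 3e5, 4e5),
                     ref_count = c(50L, 20L, 15L, 35L),
                     alt_count = c(50L, 80L, 15L, 5L))
  res <- test_snp_balance(snps)
  expect_equal(nrow(res$retained), 2)
  expect_equal(res$dropped$reason, c("depth < 40", "alt_count < 10"))
  # dead-center BAF: p = 1, balanced
  expect_equal(res$retained$balance_p[1], 1)
  expect_true(res$retained$balanced[1])
  # 80/100: overwhelming imbalance
  expect_lt(res$retained$balance_p[2], 1e-8)
  expect_false(res$retained$balanced[2])
  # closed form agrees with binom.test on a grid
  for (alt in c(10, 45, 60, 77)) {
    got <- test_snp_balance(data.frame(chrom = "chr1", pos = 1,
                                       ref_count = 100L - alt,
                                       alt_count = alt))$retained$balance_p
    expect_equal(got, stats::binom.test(alt, 100, 0.5)$p.value)
  }
})

test_that("balanced bins need both a >20% balanced fraction and enough SNPs", {
  bins <- data.frame(chrom = "chr1", start = 0:2 * 1e6, end = 1:3 * 1e6)
  snp_in_bin <- function(bin, n, n_bal) {
    data.frame(chrom = rep("chr1", n),
               pos = (bin - 1) * 1e6 + seq_len(n) * 1000,
               balanced = c(rep(TRUE, n_bal), rep(FALSE, n - n_bal)))
  }
  snps <- rbind(snp_in_bin(1, 10, 5),   # 50% balanced -> flagged
                snp_in_bin(2, 10, 1),   # 10% -> not flagged
                snp_in_bin(3, 0, 0))    # no SNPs -> not flagged
  expect_equal(identify_balanced_bins(snps, bins), c(TRUE, FALSE, FALSE))
  # exactly 20% does not pass the strict threshold
  expect_false(identify_balanced_bins(snp_in_bin(1, 10, 2), bins)[1])
  # enough balanced SNPs but below min_snps stays unflagged
  expect_false(identify_balanced_bins(snp_in_bin(1, 4, 4), bins)[1])
})

test_that("segmentation finds steps, leaves noise alone and isolates short events", {
  # constant input: one segment per chromosome
  tr <- mini_track(rep(1, 80), chrom = rep(c("chrA", "chrB"), each = 40))
  segs <- segment_ratios(tr)
  expect_equal(nrow(segs), 2)

  set.seed(4)
  x <- c(rnorm(100, 1, 0.05), rnorm(100, 1.8, 0.05))
  segs <- segment_ratios(mini_track(x))
  expect_equal(nrow(segs), 2)
  expect_lte(abs(segs$start_bin[2] - 101), 2)

  # pure noise stays unsegmented in at least 95% of replicates
  set.seed(9)
  n_single <- sum(replicate(100,
    nrow(segment_ratios(mini_track(rnorm(150, 1, 0.05)))) == 1))
  expect_gte(n_single, 95)

  # a short event mid-chromosome is split out in one interval move
  set.seed(12)
  y <- rnorm(150, 1, 0.1); y[100:106] <- rnorm(7, 2, 0.1)
  sy <- segment_ratios(mini_track(y))
  expect_equal(nrow(sy), 3)
  expect_lte(abs(sy$start_bin[2] - 100), 1)

  expect_warning(
    segment_ratios(mini_track(c(rnorm(20), rep(NA, 20)),
                              chrom = rep(c("chrA", "chrB"), each = 20),
                              masked = rep(c(FALSE, TRUE), each = 20))),
    "fully masked")
})

test_that("the mixture reference model recovers planted states", {
  set.seed(31)
  # single state
  tr <- mini_track(rnorm(500, 1, 0.05))
  m1 <- fit_reference_model(tr, rep(TRUE, 500))
  expect_equal(m1$G, 1)
  expect_equal(m1$mu, 1.0, tolerance = 0.01)

  # 60/40 mixture: the reference is the heavier component at 1.0
  tr2 <- mini_track(c(rnorm(600, 1, 0.05), rnorm(400, 1.5, 0.05)))
  m2 <- fit_reference_model(tr2, rep(TRUE, 1000))
  expect_equal(m2$G, 2)
  expect_equal(m2$mu, 1.0, tolerance = 0.02)
  expect_equal(m2$weights[m2$reference], 0.6, tolerance = 0.05)

  # constant input: sigma floor applies
  m3 <- fit_reference_model(mini_track(rep(1.25, 100)), rep(TRUE, 100))
  expect_equal(m3$sigma, 1e-4)
  expect_equal(m3$mu, 1.25)

  expect_error(fit_reference_model(tr, rep(FALSE, 500)), "balanced bins")
})

test_that("Z-test calls follow the reference model arithmetic", {
  model <- structure(list(means = 1, sds = 0.05, weights = 1, G = 1L,
                          reference = 1L, mu = 1, sigma = 0.05, n_bins = 500),
                     class = "reference_model")
  tr <- mini_track(rep(1, 30))
  segs <- data.frame(chrom = "chr1", start_bin = c(1, 11, 21),
                     end_bin = c(10, 20, 30), n_bins = 10,
                     mean_ratio = c(1.0, 1.5, 0.5))
  # bin-level sd variant: z = (1.5 - 1) / 0.05 = 10
  calls_bin <- call_gains_losses(tr, segs, model, se = "bin")
  expect_equal(calls_bin$z[11], 10)
  expect_equal(unique(calls_bin$call[1:10]), "neutral")
  expect_equal(unique(calls_bin$call[11:20]), "gain")
  expect_equal(unique(calls_bin$call[21:30]), "loss")
  # segment-level default scales by sqrt(segment length)
  calls_seg <- call_gains_losses(tr, segs, model)
  expect_equal(calls_seg$z[11], 10 * sqrt(10))
  expect_equal(calls_seg$call[11:30], calls_bin$call[11:30])
})

test_that("gene annotation uses any-overlap on half-open intervals", {
  calls <- mini_track(rep(1, 10))
  calls$call <- c(rep("gain", 3), rep("neutral", 4), rep("loss", 3))
  genes <- data.frame(gene = c("inGain", "spanning", "inNeutral", "outside"),
                      chrom = "chr1",
                      start = c(0.5e6, 2.5e6, 4.2e6, 99e6),
                      end = c(0.9e6, 3.5e6, 4.8e6, 100e6))
  expect_warning(ann <- annotate_genes(calls, genes), "outside")
  expect_equal(ann$gained, c("inGain", "spanning"))
  expect_equal(ann$lost, character(0))
  empty <- annotate_genes(calls, genes[0, ])
  expect_equal(empty$gained, character(0))
})

test_that("the full caller recovers planted events and mirrors under sign swap", {
  sc <- make_scored_pair(seed = 71, mean_depth = 200, ploidy = 4)
  res <- call_cn(sc$pair$progenitor, sc$pair$daughter, sc$pair$snps)
  sc_score <- score_calls(res$track$call, sc$events, sc$cfg$n_bins)
  expect_gte(sc_score["precision"], 0.9)
  expect_gte(sc_score["recall"], 0.9)

  # swapped signs: gains become losses, calls mirror
  cfg <- sc$cfg
  ev_m <- sc$events
  ev_m$delta <- -ev_m$delta
  ev_m$kind <- ifelse(ev_m$kind == "gain", "loss", "gain")
  pair_m <- generate_clone_pair(cfg, ploidy = 4, events = ev_m,
                                mean_depth = 200)
  res_m <- call_cn(pair_m$progenitor, pair_m$daughter, pair_m$snps)
  m_score <- score_calls(res_m$track$call, ev_m, cfg$n_bins)
  expect_gte(m_score["precision"], 0.9)
  expect_gte(m_score["recall"], 0.9)

  # normalization invariance: scaling daughter counts leaves calls unchanged
  d3 <- sc$pair$daughter
  d3$count <- d3$count * 3L
  res3 <- call_cn(sc$pair$progenitor, d3, sc$pair$snps)
  expect_equal(res3$track$call, res$track$call)
})
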