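# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths (and the base-R tests) they are checked against.

# Fisher two-sided p by brute-force enumeration of all tables with the
# observed margins, summing hypergeometric point probabilities <= that of
# the observed table (with a tiny relative tolerance for fp noise).
fisher_brute_force <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  as_range <- max(0, c1 - r2):min(r1, c1)
  pt <- function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }
  p_obs <- pt(a)
  sum(vapply(as_range, pt, 0)[vapply(as_range, pt, 0) <= p_obs * (1 + 1e-7)])
}

# Pearson chi-squared statistic via the 2x2 closed form
chisq_closed_form <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# exact one-sided Mann-Whitney p (x stochastically smaller) by enumerating
# every assignment of ranks to the x-sample
mw_exact_less <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  r <- rank(pooled)
  u_obs <- sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  combos <- utils::combn(length(pooled), length(x))
  us <- apply(combos, 2, function(idx)
    sum(rank(pooled)[idx]) - length(x) * (length(x) + 1) / 2)
  mean(us <= u_obs)
}

# scoring of planted events against a call track
score_calls <- function(calls, events, n_bins) {
  truth <- rep("neutral", n_bins)
  for (i in seq_len(nrow(events)))
    truth[events$start_bin[i]:events$end_bin[i]] <- events$kind[i]
  hit <- calls %in% c("gain", "loss")
  tp <- sum(hit & calls == truth)
  fp <- sum(hit & calls != truth)
  fn <- sum(truth %in% c("gain", "loss") & calls != truth)
  c(precision = if (tp + fp > 0) tp / (tp + fp) else 1,
    recall = if (tp + fn > 0) tp / (tp + fn) else 1)
}

# standard clone-pair scenario used across caller tests
make_scored_pair <- function(seed, mean_depth, ploidy = 3, n_bins = 3000) {
  cfg <- sim_config(seed = seed, n_bins = n_bins, n_chromosomes = 20)
  ev <- planted_events(
    chrom = c("chr2", "chr5", "chr9", "chr14", "chr17"),
    start_bin = c(200, 700, 1300, 2000, 2500),
    end_bin = c(230, 740, 1320, 2030, 2506),
    kind = c("gain", "loss", "gain", "loss", "gain"),
    delta = c(1, -1, 2, -2, 3), cfg = cfg)
  pair <- generate_clone_pair(cfg, ploidy = ploidy, events = ev,
                              mean_depth = mean_depth)
  list(cfg = cfg, events = ev, pair = pair)
}
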