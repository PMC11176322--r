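#' Per-tumor gain and loss rates
#'
#' Estimates, for every tumor in a cohort, the rate of gains and losses as
#' the fraction of the (unmasked) genome affected by each event class.
#' These rates parameterize the sampling-simulation null model of
#' [simulate_null()].
#'
#' @param states Integer matrix, bins x tumors, coded gain = +1,
#'   neutral = 0, loss = -1; `NA` marks masked bins. Alternatively an
#'   integer copy-number matrix together with `ploidy`.
#' @param ploidy Optional per-tumor ploidy vector; when given, `states` is
#'   taken as integer copy numbers and converted: CN above `round(ploidy)`
#'   is a gain, below is a loss.
#' @return Data frame `tumor, Rg, Rl` with `Rg + Rl <= 1`.
#' @export
estimate_rates <- function(states, ploidy = NULL) {
  states <- as_state_matrix(states, ploidy)
  n_ok <- colSums(!is.na(states))
  if (any(n_ok == 0L))
    stop("tumor(s) with all bins masked: ",
         paste(colnames(states)[n_ok == 0L], collapse = ", "))
  data.frame(
    tumor = colnames(states),
    Rg = colSums(states == 1L, na.rm = TRUE) / n_ok,
    Rl = colSums(states == -1L, na.rm = TRUE) / n_ok,
    row.names = NULL, stringsAsFactors = FALSE)
}

as_state_matrix <- function(states, ploidy = NULL) {
  states <- as.matrix(states)
  if (ncol(states) < 2L) stop("a cohort needs >= 2 tumors")
  if (is.null(colnames(states)))
    colnames(states) <- sprintf("tumor%03d", seq_len(ncol(states)))
  if (!is.null(ploidy)) {
    ploidy <- rep_len(ploidy, ncol(states))
    ref <- matrix(round(ploidy), nrow(states), ncol(states), byrow = TRUE)
    states <- sign(states - ref)
  }
  if (!all(states[!is.na(states)] %in% c(-1L, 0L, 1L)))
    stop("states must be coded -1 (loss), 0 (neutral), +1 (gain), or be ",
         "integer copy numbers accompanied by a ploidy vector")
  states
}

#' Sampling-simulation null distribution for recurrent SCNAs
#'
#' Builds the background distribution of per-bin alteration counts under
#' independence: in each of `n_sim` simulations, tumor `t` contributes a
#' gain with probability `Rg[t]` (and, independently, a loss with
#' probability `Rl[t]`), and the contributions are summed over tumors. The
#' recurrence thresholds are the upper bounds of the central 95% interval
#' of the simulated totals (the 97.5th empirical percentile), separately
#' for gains and losses; a bin is later declared recurrent when its
#' observed count exceeds the threshold.
#'
#' @param rates Data frame from [estimate_rates()] (columns `Rg`, `Rl`).
#' @param n_sim Number of simulations (default 1000; below 100 the
#'   percentile estimate is unstable and a warning is given).
#' @param seed Optional seed for reproducible thresholds.
#' @param prob Percentile used as the threshold; `0.975` is the upper bound
#'   of the central 95% interval, `0.95` gives the one-sided reading.
#' @return A list: `gain_null` and `loss_null` (simulated totals),
#'   `gain_threshold`, `loss_threshold`, `n_sim`.
#' @export
simulate_null <- function(rates, n_sim = 1000L, seed = NULL, prob = 0.975) {
  stopifnot(all(c("Rg", "Rl") %in% names(rates)))
  if (nrow(rates) < 2L) stop("a cohort needs >= 2 tumors")
  if (any(rates$Rg < 0 | rates$Rg > 1 | rates$Rl < 0 | rates$Rl > 1))
    stop("rates must lie in [0, 1]")
  if (n_sim < 100L) warning("n_sim < 100: percentile threshold is unstable")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(rates)
  gain_null <- vapply(seq_len(n_sim), function(i)
    sum(stats::rbinom(n, 1L, rates$Rg)), 0L)
  loss_null <- vapply(seq_len(n_sim), function(i)
    sum(stats::rbinom(n, 1L, rates$Rl)), 0L)
  list(gain_null = gain_null, loss_null = loss_null,
       gain_threshold = as.numeric(stats::quantile(gain_null, prob, type = 1)),
       loss_threshold = as.numeric(stats::quantile(loss_null, prob, type = 1)),
       n_sim = as.integer(n_sim), prob = prob)
}

#' Recurrently gained and lost regions in a cohort
#'
#' Flags each bin whose observed gain (loss) count across tumors strictly
#' exceeds the simulated null threshold, and merges adjacent flagged bins
#' on the same chromosome into recurrent regions (a flagged-bin gap is not
#' bridged).
#'
#' @inheritParams estimate_rates
#' @param null Output of [simulate_null()] on this cohort's rates.
#' @param chrom Optional per-bin chromosome labels (used for region
#'   merging); a single chromosome is assumed when absent.
#' @return A list of class `recurrence_result`: observed `gain_count` /
#'   `loss_count` per bin, thresholds, logical `recurrent_gain` /
#'   `recurrent_loss` flags, and region tables `gain_regions` /
#'   `loss_regions` (`chrom`, `start_bin`, `end_bin` as bin indices).
#' @export
recurrent_regions <- function(states, null, ploidy = NULL, chrom = NULL) {
  states <- as_state_matrix(states, ploidy)
  if (is.null(chrom)) chrom <- rep("chr1", nrow(states))
  stopifnot(length(chrom) == nrow(states))
  gain_count <- rowSums(states == 1L, na.rm = TRUE)
  loss_count <- rowSums(states == -1L, na.rm = TRUE)
  rg <- gain_count > null$gain_threshold
  rl <- loss_count > null$loss_threshold
  structure(list(gain_count = gain_count, loss_count = loss_count,
                 gain_threshold = null$gain_threshold,
                 loss_threshold = null$loss_threshold,
                 recurrent_gain = rg, recurrent_loss = rl,
                 gain_regions = merge_flags(rg, chrom),
                 loss_regions = merge_flags(rl, chrom),
                 n_sim = null$n_sim),
            class = "recurrence_result")
}

merge_flags <- function(flag, chrom) {
  if (!any(flag))
    return(data.frame(chrom = character(0), start_bin = integer(0),
                      end_bin = integer(0), stringsAsFactors = FALSE))
  idx <- which(flag)
  new_run <- c(TRUE, diff(idx) != 1L | chrom[idx[-1]] != chrom[idx[-length(idx)]])
  run <- cumsum(new_run)
  starts <- idx[new_run]
  ends <- idx[c(new_run[-1], TRUE)]
  data.frame(chrom = chrom[starts], start_bin = starts, end_bin = ends,
             stringsAsFactors = FALSE)
}

#' Signed deviation from euploidy
#'
#' Per-bin mean of the non-absolute deviation of integer copy number from
#' the euploid state 2, computed across the members of each declared group
#' of cells or tumors. Signed deviations let opposite gains and losses
#' cancel, so the track shows the direction of net SCNA pressure along the
#' genome.
#'
#' @param cn Integer copy-number matrix, bins x cells (or tumors).
#' @param groups Group label per column; one group is assumed when absent.
#' @return A matrix, bins x groups, of mean (CN - 2); empty groups are
#'   skipped with a warning.
#' @export
deviation_from_euploidy <- function(cn, groups = NULL) {
  cn <- as.matrix(cn)
  if (is.null(groups)) groups <- rep("all", ncol(cn))
  stopifnot(length(groups) == ncol(cn))
  lv <- unique(groups)
  keep <- vapply(lv, function(g) sum(groups == g) > 0L, TRUE)
  if (any(!keep)) warning("empty group(s) skipped")
  lv <- lv[keep]
  out <- vapply(lv, function(g)
    rowMeans(cn[, groups == g, drop = FALSE] - 2), numeric(nrow(cn)))
  matrix(out, nrow = nrow(cn), dimnames = list(NULL, lv))
}

#' Project a per-bin frequency track through synteny blocks
#'
#' Transfers a per-bin alteration-frequency track from one genome (e.g.
#' mouse) onto the bin grid of another (e.g. human) through a table of
#' homology blocks. Positions within a block are mapped linearly between
#' its source and target ranges; each target bin receives the
#' length-weighted mean of the source-bin values mapped into it, combining
#' across overlapping blocks. Orientation is ignored: frequencies are
#' strandless. Target bins covered by no block are `NA`.
#'
#' @param source_track Data frame `chrom, start, end, value` on the source
#'   bin grid.
#' @param blocks Data frame `source_chrom, source_start, source_end,
#'   target_chrom, target_start, target_end` (an `orientation` column is
#'   accepted and ignored).
#' @param target_bins Target bin grid (`chrom, start, end`).
#' @return `target_bins` with a `value` column added.
#' @export
project_synteny <- function(source_track, blocks, target_bins) {
  stopifnot(all(c("chrom", "start", "end", "value") %in% names(source_track)),
            all(c("source_chrom", "source_start", "source_end",
                  "target_chrom", "target_start", "target_end") %in% names(blocks)),
            all(c("chrom", "start", "end") %in% names(target_bins)))
  if (any(blocks$source_end <= blocks$source_start) ||
      any(blocks$target_end <= blocks$target_start))
    stop("malformed synteny block: non-positive length")
  wsum <- wtot <- numeric(nrow(target_bins))
  for (b in seq_len(nrow(blocks))) {
    t_rows <- which(target_bins$chrom == blocks$target_chrom[b] &
                    target_bins$start < blocks$target_end[b] &
                    target_bins$end > blocks$target_start[b])
    if (!length(t_rows)) next
    scale <- (blocks$source_end[b] - blocks$source_start[b]) /
             (blocks$target_end[b] - blocks$target_start[b])
    for (tr in t_rows) {
      t0 <- max(target_bins$start[tr], blocks$target_start[b])
      t1 <- min(target_bins$end[tr], blocks$target_end[b])
      s0 <- blocks$source_start[b] + (t0 - blocks$target_start[b]) * scale
      s1 <- blocks$source_start[b] + (t1 - blocks$target_start[b]) * scale
      s_rows <- which(source_track$chrom == blocks$source_chrom[b] &
                      source_track$start < s1 & source_track$end > s0)
      if (!length(s_rows)) next
      ov <- pmin(source_track$end[s_rows], s1) -
        pmax(source_track$start[s_rows], s0)
      val <- sum(source_track$value[s_rows] * ov) / sum(ov)
      wsum[tr] <- wsum[tr] + val * (t1 - t0)
      wtot[tr] <- wtot[tr] + (t1 - t0)
    }
  }
  out <- target_bins
  out$value <- ifelse(wtot > 0, wsum / pmax(wtot, 1e-300), NA_real_)
  out
}
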