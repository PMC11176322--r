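#' Simulation configuration for synthetic genomic data
#'
#' Builds the shared configuration object used by all synthetic-data
#' generators: a synthetic genome of `n_chromosomes` chromosomes tiled by
#' fixed-width bins, a seed that makes every generator byte-reproducible,
#' and the per-bin coverage-bias model.
#'
#' The synthetic genome has no real reference behind it: chromosomes are
#' named `chr1 ... chrN`, each carries `n_bins / n_chromosomes` bins
#' (remainders go to the first chromosomes), and bins are 0-based half-open
#' intervals of `bin_size` base pairs.
#'
#' @param seed Integer seed. Generators call `set.seed(seed)` on entry, so a
#'   fixed configuration yields identical output on every run.
#' @param n_bins Total number of genomic bins across the genome.
#' @param bin_size Bin width in base pairs (default 1 Mb, matching the
#'   binning used for whole-exome read counting).
#' @param n_chromosomes Number of chromosomes the bins are spread over.
#' @param bias_sd Standard deviation (log scale) of the shared log-normal
#'   per-bin coverage bias. The bias multiplies expected coverage in both
#'   members of a clone pair, which is what makes progenitor-normalization
#'   meaningful.
#' @param snps_per_bin Expected number of germline SNPs simulated per bin.
#'
#' @return An object of class `sim_config`: a list with the fields above
#'   plus `chrom` (per-bin chromosome label), `start` and `end` (per-bin
#'   coordinates).
#' @examples
#' cfg <- sim_config(seed = 1, n_bins = 100, n_chromosomes = 4)
#' table(cfg$chrom)
#' @export
sim_config <- function(seed, n_bins = 3000L, bin_size = 1e6, n_chromosomes = 20L,
                       bias_sd = 0.1, snps_per_bin = 20L) {
  seed <- as.integer(seed)
  n_bins <- as.integer(n_bins)
  n_chromosomes <- as.integer(n_chromosomes)
  stopifnot(length(seed) == 1L, !is.na(seed))
  if (n_chromosomes < 1L || n_bins < n_chromosomes)
    stop("need n_bins >= n_chromosomes >= 1")
  if (bias_sd < 0) stop("bias_sd must be >= 0")
  if (snps_per_bin < 0) stop("snps_per_bin must be >= 0")

  per <- rep(n_bins %/% n_chromosomes, n_chromosomes)
  rem <- n_bins %% n_chromosomes
  if (rem > 0L) per[seq_len(rem)] <- per[seq_len(rem)] + 1L
  chrom <- rep(paste0("chr", seq_len(n_chromosomes)), per)
  within <- unlist(lapply(per, seq_len)) - 1L
  structure(
    list(seed = seed, n_bins = n_bins, bin_size = bin_size,
         n_chromosomes = n_chromosomes, bias_sd = bias_sd,
         snps_per_bin = as.integer(snps_per_bin),
         chrom = chrom, start = within * bin_size, end = (within + 1L) * bin_size),
    class = "sim_config"
  )
}

#' Bin grid of a simulation configuration
#'
#' @param cfg A [sim_config()] object.
#' @return A data frame with columns `chrom`, `start`, `end`, one row per bin
#'   (0-based half-open coordinates).
#' @export
bin_grid <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  data.frame(chrom = cfg$chrom, start = cfg$start, end = cfg$end,
             stringsAsFactors = FALSE)
}

#' Planted copy-number events
#'
#' Constructs and validates a table of planted SCNA events used as ground
#' truth by the clone-pair generator. Events are expressed in bin indices
#' (1-based, inclusive, genome-wide) and must not overlap.
#'
#' @param chrom Chromosome label of each event (checked against the grid).
#' @param start_bin,end_bin First and last genome-wide bin index of each event.
#' @param kind `"gain"` or `"loss"`.
#' @param delta Integer copy-number change; positive for gains, negative for
#'   losses, never zero.
#' @param cfg Optional [sim_config()]; if supplied, event coordinates are
#'   checked against the bin grid.
#' @return A data frame of class `planted_events`.
#' @export
planted_events <- function(chrom, start_bin, end_bin, kind, delta, cfg = NULL) {
  ev <- data.frame(chrom = chrom, start_bin = as.integer(start_bin),
                   end_bin = as.integer(end_bin), kind = kind,
                   delta = as.integer(delta), stringsAsFactors = FALSE)
  if (nrow(ev)) {
    if (any(ev$delta == 0L)) stop("event delta must be nonzero")
    if (any(ev$end_bin < ev$start_bin)) stop("event end_bin before start_bin")
    bad <- (ev$delta > 0L) != (ev$kind == "gain")
    if (any(!ev$kind %in% c("gain", "loss")) || any(bad))
      stop("event kind must be 'gain'/'loss' and match the sign of delta")
    o <- order(ev$start_bin)
    ov <- which(ev$start_bin[o][-1L] <= ev$end_bin[o][-nrow(ev)])
    if (length(ov))
      stop("overlapping planted events: ",
           paste(utils::capture.output(print(ev[o, ][c(ov, ov + 1L), ])),
                 collapse = "\n"))
    if (!is.null(cfg)) {
      if (any(ev$start_bin < 1L) || any(ev$end_bin > cfg$n_bins))
        stop("planted events fall outside the bin grid")
      for (i in seq_len(nrow(ev)))
        if (!all(cfg$chrom[ev$start_bin[i]:ev$end_bin[i]] == ev$chrom[i]))
          stop("event ", i, " crosses a chromosome boundary or has wrong chrom")
    }
  }
  class(ev) <- c("planted_events", "data.frame")
  ev
}

# helper: empty event table
no_events <- function() {
  planted_events(character(0), integer(0), integer(0), character(0), integer(0))
}
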