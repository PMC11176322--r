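#' Library-size-normalized read-depth ratio track
#'
#' Computes, for every genomic bin, the ratio of daughter to progenitor
#' read counts, rescaled by the ratio of total library sizes so that a bin
#' whose copy number is unchanged between the clones has expected ratio 1:
#' `ratio_b = (daughter_b / progenitor_b) * (progenitor_total / daughter_total)`.
#' Bins with zero coverage in either sample are masked and excluded from
#' all downstream steps.
#'
#' @param progenitor,daughter Bin-count data frames (`chrom`, `start`,
#'   `end`, `count`) on identical bin grids, e.g. from
#'   [generate_clone_pair()] or [read_bin_counts()].
#' @return A data frame `chrom, start, end, ratio, masked` (class
#'   `depth_ratio_track`); `ratio` is NA where `masked`.
#' @export
compute_depth_ratio <- function(progenitor, daughter) {
  for (df in list(progenitor, daughter))
    if (!all(c("chrom", "start", "end", "count") %in% names(df)))
      stop("bin counts need columns chrom, start, end, count")
  mism <- which(progenitor$chrom != daughter$chrom |
                progenitor$start != daughter$start |
                progenitor$end != daughter$end)
  if (nrow(progenitor) != nrow(daughter) || length(mism))
    stop("bin grids differ",
         if (length(mism)) paste0("; first discrepancy at row ", mism[1]) else
           paste0(": ", nrow(progenitor), " vs ", nrow(daughter), " bins"))
  if (any(progenitor$count < 0) || any(daughter$count < 0))
    stop("counts must be >= 0")
  ptot <- sum(as.numeric(progenitor$count))
  dtot <- sum(as.numeric(daughter$count))
  if (ptot == 0 || dtot == 0) stop("a sample has zero total reads")
  masked <- progenitor$count == 0L | daughter$count == 0L
  ratio <- ifelse(masked, NA_real_,
                  (daughter$count / progenitor$count) * (ptot / dtot))
  structure(data.frame(chrom = progenitor$chrom, start = progenitor$start,
                       end = progenitor$end, ratio = ratio, masked = masked,
                       stringsAsFactors = FALSE),
            class = c("depth_ratio_track", "data.frame"))
}

#' Test SNPs for allelic balance
#'
#' Filters putative heterozygous SNPs to those with coverage depth of at
#' least `min_depth` and alternate-allele count of at least `min_alt`, then
#' tests each retained SNP for allelic balance with an exact two-sided
#' binomial test of the alt count against a B-allele frequency of 0.5. A
#' SNP is called balanced when the test cannot reject balance at `alpha`.
#'
#' @param snps Data frame `chrom, pos, ref_count, alt_count`.
#' @param alpha Significance threshold for rejecting balance.
#' @param min_depth,min_alt Depth and alt-count retention filters.
#' @return A list: `retained` (SNPs with `depth`, `baf`, `balance_p`,
#'   `balanced` added) and `dropped` (filtered-out records with a `reason`).
#' @export
test_snp_balance <- function(snps, alpha = 0.05, min_depth = 40L, min_alt = 10L) {
  stopifnot(all(c("chrom", "pos", "ref_count", "alt_count") %in% names(snps)))
  depth <- snps$ref_count + snps$alt_count
  keep <- depth >= min_depth & snps$alt_count >= min_alt
  dropped <- snps[!keep, , drop = FALSE]
  if (nrow(dropped))
    dropped$reason <- ifelse(depth[!keep] < min_depth,
                             sprintf("depth < %d", min_depth),
                             sprintf("alt_count < %d", min_alt))
  ret <- snps[keep, , drop = FALSE]
  ret$depth <- depth[keep]
  ret$baf <- ret$alt_count / ret$depth
  # exact two-sided binomial p at rate 0.5: the distribution is symmetric,
  # so both tails collapse to one closed form (equals binom.test exactly)
  m <- pmin(ret$alt_count, ret$depth - ret$alt_count)
  ret$balance_p <- pmin(1, 2 * stats::pbinom(m, ret$depth, 0.5) -
                          ifelse(2 * m == ret$depth,
                                 stats::dbinom(m, ret$depth, 0.5), 0))
  ret$balanced <- ret$balance_p >= alpha
  rownames(ret) <- rownames(dropped) <- NULL
  list(retained = ret, dropped = dropped)
}

#' Flag allelic-balanced bins from SNP evidence
#'
#' A bin is flagged allelic-balanced when more than `min_fraction` of its
#' retained SNPs are individually consistent with a B-allele frequency of
#' 0.5 and the bin holds at least `min_snps` retained SNPs (the fraction
#' threshold tolerates somatic variants and miscalled homozygous SNPs among
#' the putative heterozygous sites). Bins with too few SNPs stay unflagged:
#' absence of evidence is not treated as balance.
#'
#' @param snps The `retained` element of [test_snp_balance()].
#' @param bins Bin grid data frame (`chrom`, `start`, `end`).
#' @param min_fraction Strict lower bound on the balanced-SNP fraction.
#' @param min_snps Minimum retained SNPs per bin.
#' @return Logical vector, one flag per bin.
#' @export
identify_balanced_bins <- function(snps, bins, min_fraction = 0.20,
                                   min_snps = 5L) {
  stopifnot(all(c("balanced", "chrom", "pos") %in% names(snps)))
  n_tot <- n_bal <- integer(nrow(bins))
  idx <- assign_to_bins(snps$chrom, snps$pos, bins)
  ok <- !is.na(idx)
  tt <- table(factor(idx[ok], levels = seq_len(nrow(bins))))
  tb <- table(factor(idx[ok & snps$balanced], levels = seq_len(nrow(bins))))
  n_tot <- as.integer(tt)
  n_bal <- as.integer(tb)
  n_tot >= min_snps & n_bal / pmax(n_tot, 1L) > min_fraction
}

# map (chrom, pos) to row index of a half-open bin grid; NA when outside
assign_to_bins <- function(chrom, pos, bins) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(bins$chrom)) {
    rows <- which(bins$chrom == ch)
    sel <- which(chrom == ch)
    if (!length(sel)) next
    j <- findInterval(pos[sel], bins$start[rows])
    valid <- j >= 1L & j <= length(rows)
    valid[valid] <- pos[sel][valid] < bins$end[rows[j[valid]]]
    idx[sel[valid]] <- rows[j[valid]]
  }
  idx
}

#' Segment a depth-ratio track into constant-ratio regions
#'
#' Per-chromosome changepoint segmentation of the unmasked read-depth
#' ratios by recursive interval splitting in the circular-binary-
#' segmentation style: at each step the interval whose mean differs most
#' from its complement (two changepoints tested jointly, so short SCNAs in
#' the middle of a chromosome are found in one move) is split off when the
#' gain in Gaussian log-likelihood exceeds a BIC-style penalty (default
#' `5 * log(n)` per chromosome). Neighbouring bins affected by the same
#' SCNA end up in one segment with a common mean ratio.
#'
#' @param track A [compute_depth_ratio()] track.
#' @param penalty Split-acceptance penalty; `NULL` for the default
#'   `5 * log(n)` with `n` the chromosome's unmasked bin count.
#' @param min_seg_len Minimum segment length in bins.
#' @return Data frame of segments: `chrom`, `start_bin`, `end_bin`
#'   (row indices into `track`, inclusive), `n_bins` (unmasked members) and
#'   `mean_ratio`. Fully masked chromosomes are skipped with a warning.
#' @export
segment_ratios <- function(track, penalty = NULL, min_seg_len = 3L) {
  stopifnot(inherits(track, "depth_ratio_track") ||
              all(c("chrom", "ratio", "masked") %in% names(track)))
  segs <- list()
  for (ch in unique(track$chrom)) {
    rows <- which(track$chrom == ch & !track$masked)
    if (!length(rows)) {
      warning("chromosome ", ch, " fully masked; skipped")
      next
    }
    x <- track$ratio[rows]
    pen <- if (is.null(penalty)) 5 * log(length(x)) else penalty
    bounds <- binseg(x, pen, min_seg_len)
    for (k in seq_len(nrow(bounds))) {
      member <- rows[bounds[k, 1]:bounds[k, 2]]
      segs[[length(segs) + 1L]] <- data.frame(
        chrom = ch, start_bin = member[1], end_bin = member[length(member)],
        n_bins = length(member), mean_ratio = mean(track$ratio[member]),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# best interval-vs-complement split (two changepoints tested jointly, the
# complement acting as a single arc); returns interval bounds and the
# log-likelihood gain, or NULL when the vector is too short
best_interval <- function(x, min_len) {
  n <- length(x)
  if (n < 2L * min_len) return(NULL)
  cs <- c(0, cumsum(x))
  tot <- cs[n + 1L]
  tot2 <- sum(x^2)
  rss0 <- tot2 - tot^2 / n
  best <- list(gain = -Inf)
  for (i in seq_len(n - min_len + 1L)) {
    j <- (i + min_len - 1L):n
    L <- j - i + 1L
    Lc <- n - L
    ok <- (Lc >= min_len | Lc == 0L) & L < n
    if (!any(ok)) next
    S <- cs[j + 1L] - cs[i]
    Sc <- tot - S
    expl <- S^2 / L + ifelse(Lc > 0L, Sc^2 / Lc, 0)
    expl[!ok] <- -Inf
    k <- which.max(expl)
    rss1 <- tot2 - expl[k]
    gain <- n * (log(max(rss0, 1e-300) / n) - log(max(rss1, 1e-300) / n))
    if (gain > best$gain) best <- list(i = i, j = j[k], gain = gain)
  }
  if (!is.finite(best$gain)) return(NULL)
  best
}

# recursive segmentation; returns matrix of (first, last) index pairs
binseg <- function(x, penalty, min_len) {
  queue <- list(c(1L, length(x)))
  out <- list()
  while (length(queue)) {
    s <- queue[[1]]
    queue <- queue[-1]
    sp <- best_interval(x[s[1]:s[2]], min_len)
    if (is.null(sp) || sp$gain <= penalty) {
      out[[length(out) + 1L]] <- s
      next
    }
    i <- s[1] + sp$i - 1L
    j <- s[1] + sp$j - 1L
    parts <- list()
    if (i > s[1]) parts <- c(parts, list(c(s[1], i - 1L)))
    parts <- c(parts, list(c(i, j)))
    if (j < s[2]) parts <- c(parts, list(c(j + 1L, s[2])))
    queue <- c(parts, queue)
  }
  m <- do.call(rbind, out)
  m[order(m[, 1]), , drop = FALSE]
}

#' Fit the Gaussian-mixture reference model of balanced-bin ratios
#'
#' Models the read-depth ratios of allelic-balanced bins as a Gaussian
#' mixture (one component per copy-number state present among balanced
#' regions), with the component count selected by BIC over `1:max_components`.
#' The largest-weight component is taken as the reference distribution: the
#' ratio level of the unaltered genome, against which gains and losses are
#' subsequently tested.
#'
#' The mixture is fitted to log ratios: a ratio of Poisson counts is
#' right-skewed, and on the raw scale BIC reliably splits a single
#' copy-number state into two spurious components, biasing the reference.
#' On the log scale the per-state distribution is close to Gaussian at the
#' bin counts this caller targets. The selected reference component is
#' converted back to the ratio scale through the lognormal moments, so
#' `mu` and `sigma` remain directly comparable with segment mean ratios.
#'
#' @param track A [compute_depth_ratio()] track.
#' @param balanced_bins Logical flag per bin ([identify_balanced_bins()]).
#' @param max_components Largest mixture size tried.
#' @param min_balanced Minimum number of unmasked balanced bins required.
#' @param sigma_floor Lower bound applied to the reference sd to avoid a
#'   degenerate component on (near-)constant input.
#' @return An object of class `reference_model`: `means`, `sds`, `weights`,
#'   `G`, `reference` (component index), `mu`, `sigma`, `n_bins`.
#' @importFrom mclust Mclust mclustBIC
#' @export
fit_reference_model <- function(track, balanced_bins, max_components = 5L,
                                min_balanced = 50L, sigma_floor = 1e-4) {
  use <- balanced_bins & !track$masked
  r <- track$ratio[use]
  if (length(r) < min_balanced)
    stop("only ", length(r), " balanced bins (need >= ", min_balanced,
         "); relax the SNP-balance or min_snps parameters")
  if (stats::sd(r) < sigma_floor) {
    model <- list(means = mean(r), sds = sigma_floor, weights = 1, G = 1L)
  } else {
    fit <- mclust::Mclust(log(r), G = seq_len(max_components),
                          modelNames = "V", verbose = FALSE)
    if (is.null(fit)) stop("mixture fit failed on balanced-bin ratios")
    sq <- fit$parameters$variance$sigmasq
    sq <- rep_len(sq, fit$G)
    m <- unname(fit$parameters$mean)
    s2 <- pmax(unname(sq), sigma_floor^2)
    # lognormal moments: back to the ratio scale
    model <- list(means = exp(m + s2 / 2),
                  sds = pmax(sqrt((exp(s2) - 1) * exp(2 * m + s2)), sigma_floor),
                  weights = unname(fit$parameters$pro), G = fit$G)
  }
  ref <- which.max(model$weights)
  structure(c(model, list(reference = ref, mu = model$means[ref],
                          sigma = max(model$sds[ref], sigma_floor),
                          n_bins = length(r))),
            class = "reference_model")
}

#' @export
print.reference_model <- function(x, ...) {
  cat(sprintf("Gaussian mixture reference model (%d component%s, %d balanced bins)\n",
              x$G, if (x$G > 1) "s" else "", x$n_bins))
  for (i in seq_len(x$G))
    cat(sprintf("  %s mu = %.4f, sigma = %.4f, weight = %.3f\n",
                if (i == x$reference) "[ref]" else "     ",
                x$means[i], x$sds[i], x$weights[i]))
  invisible(x)
}

#' Call per-bin copy-number gains and losses against the reference
#'
#' Tests each bin's segment mean ratio against the reference distribution
#' with a two-sided Z-test at significance `alpha`; rejected bins are
#' called gained or lost according to whether the segment mean lies above
#' or below the reference mean. By default the standard error of a segment
#' mean over `L` bins, `sigma / sqrt(L)`, is used (`se = "segment"`); with
#' `se = "bin"` the raw bin-level reference sd is used instead, which
#' reproduces the more conservative bin-wise test but has little power
#' against small copy-number shifts at moderate depth.
#'
#' @param track A [compute_depth_ratio()] track.
#' @param segments Output of [segment_ratios()] on the same track.
#' @param model A [fit_reference_model()] object.
#' @param alpha Two-sided significance level (default 0.1%, chosen so the
#'   expected number of false-positive 1 Mb bins per genome stays low
#'   without further multiple-testing correction).
#' @param se Standard error used in the Z-test (see above).
#' @return A data frame `chrom, start, end, ratio, segment, seg_mean, z, p,
#'   call` with `call` in `gain`, `neutral`, `loss`, `masked` (class
#'   `cn_call_track`).
#' @export
call_gains_losses <- function(track, segments, model, alpha = 0.001,
                              se = c("segment", "bin")) {
  se <- match.arg(se)
  stopifnot(inherits(model, "reference_model"))
  if (model$sigma <= 0) stop("reference sigma is zero")
  out <- data.frame(chrom = track$chrom, start = track$start, end = track$end,
                    ratio = track$ratio, segment = NA_integer_,
                    seg_mean = NA_real_, z = NA_real_, p = NA_real_,
                    call = ifelse(track$masked, "masked", "neutral"),
                    stringsAsFactors = FALSE)
  for (k in seq_len(nrow(segments))) {
    member <- segments$start_bin[k]:segments$end_bin[k]
    member <- member[!track$masked[member]]
    denom <- if (se == "segment") model$sigma / sqrt(segments$n_bins[k])
             else model$sigma
    z <- (segments$mean_ratio[k] - model$mu) / denom
    p <- 2 * stats::pnorm(-abs(z))
    out$segment[member] <- k
    out$seg_mean[member] <- segments$mean_ratio[k]
    out$z[member] <- z
    out$p[member] <- p
    out$call[member] <- if (p >= alpha) "neutral"
      else if (z > 0) "gain" else "loss"
  }
  class(out) <- c("cn_call_track", "data.frame")
  out
}

#' Annotate gained and lost genes
#'
#' A gene is reported gained (lost) when any bin it overlaps carries a gain
#' (loss) call; overlap is half-open interval intersection on the shared
#' genome layout. Genes falling entirely outside the bin grid are skipped
#' with a warning.
#'
#' @param calls A [call_gains_losses()] track.
#' @param genes Data frame `gene, chrom, start, end`.
#' @return A list with character vectors `gained` and `lost` and the
#'   per-gene annotation `table`.
#' @export
annotate_genes <- function(calls, genes) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(genes)))
  status <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit <- calls$chrom == genes$chrom[i] &
      calls$start < genes$end[i] & calls$end > genes$start[i]
    if (!any(hit)) {
      status[i] <- NA_character_
      next
    }
    cl <- calls$call[hit]
    status[i] <- if (any(cl == "gain")) "gain"
      else if (any(cl == "loss")) "loss" else "neutral"
  }
  if (anyNA(status))
    warning("gene(s) outside the bin grid skipped: ",
            paste(genes$gene[is.na(status)], collapse = ", "))
  tab <- cbind(genes, status = status)
  list(gained = genes$gene[!is.na(status) & status == "gain"],
       lost = genes$gene[!is.na(status) & status == "loss"],
       table = tab)
}

#' Progenitor-referenced copy-number calling pipeline
#'
#' Runs the four-step caller end to end: (1) library-size-normalized
#' daughter/progenitor depth ratios with zero-coverage masking, (2) SNP
#' heterozygosity/allelic-balance testing and balanced-bin identification,
#' (3) changepoint segmentation of the ratio track, and (4) a Gaussian
#' mixture fitted to balanced-bin ratios whose largest component serves as
#' the reference distribution for two-sided Z-tests that call each bin
#' gained, neutral or lost. The output is a per-bin call track of SCNAs
#' acquired by the daughter clone relative to its progenitor — no matched
#' normal is needed.
#'
#' @inheritParams compute_depth_ratio
#' @param snps SNP allele-count table (`chrom,pos,ref_count,alt_count`).
#' @param alpha Z-test significance level.
#' @param genes Optional gene table for [annotate_genes()].
#' @param balance_alpha,min_depth,min_alt SNP filters
#'   (see [test_snp_balance()]).
#' @param min_fraction,min_snps Balanced-bin rule
#'   (see [identify_balanced_bins()]).
#' @param penalty,min_seg_len Segmentation control ([segment_ratios()]).
#' @param se Z-test standard error variant ([call_gains_losses()]).
#' @return A list: `track` (per-bin calls), `segments`, `model`,
#'   `balanced_bins`, `ratio` (the depth-ratio track), and `genes` when a
#'   gene table was supplied.
#' @examples
#' cfg <- sim_config(seed = 11, n_bins = 400, n_chromosomes = 4)
#' ev <- planted_events("chr2", 120, 160, "gain", 2, cfg)
#' pair <- generate_clone_pair(cfg, ploidy = 2, events = ev, mean_depth = 200)
#' res <- call_cn(pair$progenitor, pair$daughter, pair$snps)
#' table(res$track$call)
#' @export
call_cn <- function(progenitor, daughter, snps, alpha = 0.001, genes = NULL,
                    balance_alpha = 0.05, min_depth = 40L, min_alt = 10L,
                    min_fraction = 0.20, min_snps = 5L,
                    penalty = NULL, min_seg_len = 3L,
                    se = c("segment", "bin")) {
  track <- compute_depth_ratio(progenitor, daughter)
  snp_res <- test_snp_balance(snps, alpha = balance_alpha,
                              min_depth = min_depth, min_alt = min_alt)
  balanced <- identify_balanced_bins(snp_res$retained, track,
                                     min_fraction = min_fraction,
                                     min_snps = min_snps)
  segments <- segment_ratios(track, penalty = penalty,
                             min_seg_len = min_seg_len)
  model <- fit_reference_model(track, balanced)
  calls <- call_gains_losses(track, segments, model, alpha = alpha, se = se)
  out <- list(track = calls, segments = segments, model = model,
              balanced_bins = balanced, ratio = track)
  if (!is.null(genes)) out$genes <- annotate_genes(calls, genes)
  out
}
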