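#' Simulate a progenitor/daughter clone pair with planted SCNAs
#'
#' Generates binned sequencing coverage for a single-cell-derived progenitor
#' clone and a daughter clone that has acquired the planted copy-number
#' events, plus a table of germline heterozygous SNP allele counts. This is
#' the input expected by the progenitor-referenced copy-number caller
#' ([call_cn()]).
#'
#' Coverage model: each bin has a log-normal multiplicative bias (sd
#' `cfg$bias_sd`) shared between the two clones; read counts are Poisson
#' with mean `mean_depth * bias`, scaled in the daughter by
#' `(ploidy + delta) / ploidy` inside planted events. SNPs are placed
#' uniformly across bins; alt counts are Binomial(depth, 0.5) in
#' allelic-balanced (non-event) bins and Binomial(depth, `event_baf`) inside
#' events, emulating allelic imbalance over acquired SCNAs.
#'
#' @param cfg A [sim_config()]; `cfg$seed` fixes the whole draw.
#' @param ploidy Background integer ploidy of the progenitor clone.
#' @param events A [planted_events()] table (non-overlapping; deltas must
#'   keep copy number positive: `delta > -ploidy`).
#' @param mean_depth Expected reads per bin in the progenitor.
#' @param n_snps Number of simulated SNPs (default `snps_per_bin * n_bins`).
#' @param event_baf Planted B-allele frequency inside event bins (must not
#'   be 0.5).
#'
#' @return A list with elements `progenitor` and `daughter` (data frames
#'   `chrom,start,end,count` with a `sample_id` attribute), `snps`
#'   (`chrom,pos,ref_count,alt_count`), `truth` (the event table plus the
#'   planted ploidy as attribute `ploidy`), and `bins` (the grid).
#' @examples
#' cfg <- sim_config(seed = 7, n_bins = 200, n_chromosomes = 4)
#' ev <- planted_events("chr1", 5, 20, "gain", 2, cfg)
#' pair <- generate_clone_pair(cfg, ploidy = 3, events = ev, mean_depth = 150)
#' @export
generate_clone_pair <- function(cfg, ploidy = 2L, events = NULL,
                                mean_depth = 200, n_snps = NULL,
                                event_baf = 0.8) {
  stopifnot(inherits(cfg, "sim_config"))
  if (mean_depth <= 0) stop("mean_depth must be > 0")
  if (is.null(events)) events <- no_events()
  if (!inherits(events, "planted_events"))
    events <- planted_events(events$chrom, events$start_bin, events$end_bin,
                             events$kind, events$delta, cfg)
  # re-validate against this grid even for prebuilt tables
  planted_events(events$chrom, events$start_bin, events$end_bin,
                 events$kind, events$delta, cfg)
  if (any(events$delta <= -ploidy))
    stop("planted losses would drive copy number to zero or below")
  if (event_baf == 0.5) stop("event_baf must differ from 0.5")
  if (is.null(n_snps)) n_snps <- cfg$snps_per_bin * cfg$n_bins
  set.seed(cfg$seed)

  n <- cfg$n_bins
  bias <- exp(stats::rnorm(n, 0, cfg$bias_sd))
  cn_factor <- rep(1, n)
  in_event <- rep(FALSE, n)
  for (i in seq_len(nrow(events))) {
    idx <- events$start_bin[i]:events$end_bin[i]
    cn_factor[idx] <- (ploidy + events$delta[i]) / ploidy
    in_event[idx] <- TRUE
  }
  prog <- stats::rpois(n, mean_depth * bias)
  daug <- stats::rpois(n, mean_depth * bias * cn_factor)

  snp_bin <- sample.int(n, n_snps, replace = TRUE)
  pos <- cfg$start[snp_bin] +
    floor(stats::runif(n_snps) * (cfg$end[snp_bin] - cfg$start[snp_bin]))
  depth <- stats::rpois(n_snps, mean_depth)
  baf <- ifelse(in_event[snp_bin], event_baf, 0.5)
  alt <- stats::rbinom(n_snps, depth, baf)
  snps <- data.frame(chrom = cfg$chrom[snp_bin], pos = pos,
                     ref_count = depth - alt, alt_count = alt,
                     stringsAsFactors = FALSE)
  snps <- snps[order(match(snps$chrom, unique(cfg$chrom)), snps$pos), ]
  rownames(snps) <- NULL

  grid <- bin_grid(cfg)
  truth <- events
  attr(truth, "ploidy") <- ploidy
  list(progenitor = as_bin_counts(grid, prog, "progenitor"),
       daughter = as_bin_counts(grid, daug, "daughter"),
       snps = snps, truth = truth, bins = grid)
}

as_bin_counts <- function(grid, counts, sample_id) {
  out <- grid
  out$count <- as.integer(counts)
  attr(out, "sample_id") <- sample_id
  out
}

#' Simulate a single-cell copy-number matrix for one tumor
#'
#' Draws `n_cells` cells from a tumor founded by the copy-number profile
#' `founder`. True tumor cells diverge from the founder by chromosome
#' missegregation: whole-chromosome +/-1 events whose expected genome
#' fraction is `divergence_rate`, the dominant mode of ongoing CIN in these
#' tumors (cells therefore share the founder's breakpoints and acquire few
#' private ones). A fraction of tumor cells carries an extra whole-genome
#' doubling; contaminant cells are flat diploid (normal
#' epithelium/lymphocytes); noisy cells carry extensive segmental changes
#' with breakpoints independent of the founder, emulating S-phase,
#' low-coverage or doublet artifacts.
#'
#' Cell labels are drawn independently per cell with the given fractions,
#' so realized class counts fluctuate binomially around their expectation.
#'
#' @param cfg A [sim_config()].
#' @param n_cells Number of cells (>= 2).
#' @param founder Integer copy-number profile of length `cfg$n_bins`;
#'   default: [random_founder_profile()] on a diploid background.
#' @param divergence_rate Expected fraction of the genome altered per tumor
#'   cell relative to the founder.
#' @param wgd_fraction Fraction of tumor cells whose founder profile is
#'   doubled before divergence.
#' @param contaminant_fraction,noisy_fraction Fractions of diploid
#'   contaminant and noisy cells (fractions must sum to at most 1).
#' @param noisy_rate Expected altered genome fraction for noisy cells.
#' @return A list with `cn` (integer matrix, bins x cells), `truth`
#'   (data frame `cell_id,label,wgd`) and `bins`.
#' @export
generate_single_cell_tumor <- function(cfg, n_cells, founder = NULL,
                                       divergence_rate = 0.05,
                                       wgd_fraction = 0,
                                       contaminant_fraction = 0,
                                       noisy_fraction = 0,
                                       noisy_rate = 0.5) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_cells < 2L) stop("n_cells must be >= 2 (pairwise metrics undefined)")
  fr <- c(contaminant_fraction, noisy_fraction, wgd_fraction, divergence_rate, noisy_rate)
  if (any(fr < 0) || any(fr[1:3] > 1)) stop("fractions must lie in [0, 1]")
  if (contaminant_fraction + noisy_fraction > 1)
    stop("contaminant_fraction + noisy_fraction exceed 1")
  set.seed(cfg$seed)
  if (is.null(founder)) founder <- random_founder_profile(cfg)
  stopifnot(length(founder) == cfg$n_bins, all(founder >= 0))

  label <- sample(c("contaminant", "noisy", "tumor"), n_cells, replace = TRUE,
                  prob = c(contaminant_fraction, noisy_fraction,
                           1 - contaminant_fraction - noisy_fraction))
  wgd <- label == "tumor" & stats::runif(n_cells) < wgd_fraction
  cn <- matrix(0L, nrow = cfg$n_bins, ncol = n_cells,
               dimnames = list(NULL, sprintf("cell%03d", seq_len(n_cells))))
  for (j in seq_len(n_cells)) {
    cn[, j] <- switch(label[j],
      contaminant = rep(2L, cfg$n_bins),
      noisy = diverge_profile(cfg, rep(2L, cfg$n_bins), noisy_rate,
                              mean_len = 60L, max_delta = 2L),
      tumor = missegregate_profile(cfg, if (wgd[j]) 2L * founder else founder,
                                   divergence_rate))
  }
  list(cn = cn,
       truth = data.frame(cell_id = colnames(cn), label = label, wgd = wgd,
                          stringsAsFactors = FALSE),
       bins = bin_grid(cfg))
}

#' Random aneuploid founder profile
#'
#' A background-`ploidy` profile with `n_events` random segmental events,
#' used as the default tumor founder in [generate_single_cell_tumor()].
#'
#' @inheritParams generate_single_cell_tumor
#' @param n_events Number of segmental events planted in the founder.
#' @param ploidy Background copy number.
#' @param mean_len Mean event length in bins.
#' @return An integer vector of length `cfg$n_bins`.
#' @export
random_founder_profile <- function(cfg, n_events = 12L, ploidy = 2L,
                                   mean_len = 40L) {
  prof <- rep(as.integer(ploidy), cfg$n_bins)
  for (i in seq_len(n_events)) {
    len <- 1L + stats::rgeom(1L, 1 / mean_len)
    s <- sample.int(cfg$n_bins - len + 1L, 1L)
    idx <- s:(s + len - 1L)
    idx <- idx[cfg$chrom[idx] == cfg$chrom[s]]
    prof[idx] <- pmax(0L, prof[idx] + sample(c(-1L, 1L), 1L))
  }
  prof
}

# whole-chromosome missegregation events; expected altered genome
# fraction is `rate`
missegregate_profile <- function(cfg, profile, rate) {
  prof <- as.integer(profile)
  if (rate <= 0) return(prof)
  n_ev <- stats::rpois(1L, rate * cfg$n_chromosomes)
  chroms <- unique(cfg$chrom)
  for (i in seq_len(n_ev)) {
    ch <- sample(chroms, 1L)
    idx <- which(cfg$chrom == ch)
    prof[idx] <- pmax(0L, prof[idx] + sample(c(-1L, 1L), 1L))
  }
  prof
}

# apply random segmental +/-delta events to a profile until the expected
# altered fraction is `rate`; events stay within one chromosome
diverge_profile <- function(cfg, profile, rate, mean_len = 10L, max_delta = 1L) {
  prof <- as.integer(profile)
  if (rate <= 0) return(prof)
  n_ev <- stats::rpois(1L, rate * cfg$n_bins / mean_len)
  for (i in seq_len(n_ev)) {
    len <- 1L + stats::rgeom(1L, 1 / mean_len)
    s <- sample.int(cfg$n_bins - min(len, cfg$n_bins) + 1L, 1L)
    idx <- s:min(s + len - 1L, cfg$n_bins)
    idx <- idx[cfg$chrom[idx] == cfg$chrom[s]]
    delta <- sample(c(-seq_len(max_delta), seq_len(max_delta)), 1L)
    prof[idx] <- pmax(0L, prof[idx] + delta)
  }
  prof
}

#' Simulate a cohort of per-tumor copy-number state profiles
#'
#' Each tumor alters each bin independently: a gain with probability
#' `gain_rate`, else a loss with probability `loss_rate`, else neutral.
#' Bins listed in `recurrent_bins` are additionally driven to the
#' `recurrent_kind` state with probability `recurrent_rate`, planting a
#' recurrently altered region against the background rates.
#'
#' @param cfg A [sim_config()].
#' @param n_tumors Number of tumors (>= 2).
#' @param gain_rate,loss_rate Per-bin alteration probabilities; scalars or
#'   length-`n_tumors` vectors. `gain_rate + loss_rate` must be <= 1 per tumor.
#' @param recurrent_bins Genome-wide bin indices with a boosted rate.
#' @param recurrent_rate Probability that a recurrent bin is altered in a
#'   given tumor.
#' @param recurrent_kind `"gain"` or `"loss"`.
#' @return A list with `states` (integer matrix, bins x tumors, coded
#'   gain = +1, neutral = 0, loss = -1), `truth` (rates and recurrent bins)
#'   and `bins`.
#' @export
generate_cohort_profiles <- function(cfg, n_tumors, gain_rate, loss_rate,
                                     recurrent_bins = integer(0),
                                     recurrent_rate = 0.9,
                                     recurrent_kind = c("gain", "loss")) {
  stopifnot(inherits(cfg, "sim_config"))
  if (n_tumors < 2L) stop("n_tumors must be >= 2")
  recurrent_kind <- match.arg(recurrent_kind)
  gain_rate <- rep_len(gain_rate, n_tumors)
  loss_rate <- rep_len(loss_rate, n_tumors)
  if (any(gain_rate < 0 | gain_rate > 1 | loss_rate < 0 | loss_rate > 1) ||
      any(gain_rate + loss_rate > 1))
    stop("rates must lie in [0,1] with gain_rate + loss_rate <= 1")
  if (length(recurrent_bins) &&
      (min(recurrent_bins) < 1L || max(recurrent_bins) > cfg$n_bins))
    stop("recurrent_bins outside the bin grid")
  set.seed(cfg$seed)

  n <- cfg$n_bins
  states <- matrix(0L, nrow = n, ncol = n_tumors,
                   dimnames = list(NULL, sprintf("tumor%03d", seq_len(n_tumors))))
  for (t in seq_len(n_tumors)) {
    u <- stats::runif(n)
    st <- integer(n)
    st[u < gain_rate[t]] <- 1L
    st[u >= gain_rate[t] & u < gain_rate[t] + loss_rate[t]] <- -1L
    if (length(recurrent_bins)) {
      hit <- stats::runif(length(recurrent_bins)) < recurrent_rate
      st[recurrent_bins[hit]] <- if (recurrent_kind == "gain") 1L else -1L
    }
    states[, t] <- st
  }
  list(states = states,
       truth = list(gain_rate = gain_rate, loss_rate = loss_rate,
                    recurrent_bins = as.integer(recurrent_bins),
                    recurrent_rate = recurrent_rate,
                    recurrent_kind = recurrent_kind),
       bins = bin_grid(cfg))
}

#' Simulate longitudinal lesion diameters with planted response categories
#'
#' Generates a per-lesion table of baseline and follow-up diameters for a
#' cohort of patients, each planted with one of four response categories:
#' `homogeneous` (at least one lesion shrinking by more than 30%, all others
#' below +10% growth, no new lesions), `mixed_existing` (a responding and a
#' progressing lesion), `mixed_new_lesion` (a responding lesion plus a
#' lesion absent at baseline), and `non_responder` (no lesion reaching the
#' -30% response threshold). Planted percent changes stay at least 5
#' percentage points away from the -30/+10 decision boundaries so that at
#' `noise_sd = 0` the classifier in [classify_cohort()] recovers every
#' planted category exactly.
#'
#' @param cfg A [sim_config()] (only `seed` is used).
#' @param n_patients Number of patients.
#' @param lesions_per_patient Length-2 integer range of measurable lesions
#'   per patient; the minimum must be >= 2 so mixed responses are assessable.
#' @param category_mix Named proportions over the four categories
#'   (must sum to 1).
#' @param noise_sd Gaussian noise (percentage points) added to each lesion's
#'   percent change.
#' @return A list with `lesions` (data frame `patient_id, lesion_id,
#'   baseline_diameter, followup_diameter, is_new`) and `truth`
#'   (`patient_id, category`).
#' @export
generate_lesion_cohort <- function(cfg, n_patients,
                                   lesions_per_patient = c(2L, 8L),
                                   category_mix = c(homogeneous = 0.4,
                                                    mixed_existing = 0.3,
                                                    mixed_new_lesion = 0.1,
                                                    non_responder = 0.2),
                                   noise_sd = 0) {
  stopifnot(inherits(cfg, "sim_config"))
  cats <- c("homogeneous", "mixed_existing", "mixed_new_lesion", "non_responder")
  if (is.null(names(category_mix))) names(category_mix) <- cats
  category_mix <- category_mix[cats]
  if (anyNA(category_mix) || abs(sum(category_mix) - 1) > 1e-8 ||
      any(category_mix < 0))
    stop("category_mix must be non-negative proportions over ",
         paste(cats, collapse = ", "), " summing to 1")
  if (lesions_per_patient[1] < 2L)
    stop("lesions_per_patient minimum must be >= 2: mixed responses can only ",
         "be assessed when two or more target lesions are measurable")
  set.seed(cfg$seed)

  rows <- vector("list", n_patients)
  truth <- character(n_patients)
  for (p in seq_len(n_patients)) {
    pid <- sprintf("P%03d", p)
    k <- sample(seq(lesions_per_patient[1], lesions_per_patient[2]), 1L)
    cat_p <- sample(cats, 1L, prob = category_mix)
    truth[p] <- cat_p
    change <- switch(cat_p,
      homogeneous = c(stats::runif(1, -80, -35), stats::runif(k - 1, -80, 4)),
      mixed_existing = c(stats::runif(1, -80, -35), stats::runif(1, 16, 60),
                         if (k > 2) stats::runif(k - 2, -80, 4)),
      mixed_new_lesion = c(stats::runif(1, -80, -35),
                           stats::runif(k - 1, -80, 4)),
      non_responder = stats::runif(k, -24, 40))
    base <- stats::runif(k, 8, 40)
    change <- change + stats::rnorm(k, 0, noise_sd)
    les <- data.frame(patient_id = pid,
                      lesion_id = sprintf("%s_L%02d", pid, seq_len(k)),
                      baseline_diameter = base,
                      followup_diameter = pmax(0, base * (1 + change / 100)),
                      is_new = FALSE, stringsAsFactors = FALSE)
    if (cat_p == "mixed_new_lesion")
      les <- rbind(les, data.frame(patient_id = pid,
                                   lesion_id = sprintf("%s_NEW", pid),
                                   baseline_diameter = 0,
                                   followup_diameter = stats::runif(1, 5, 15),
                                   is_new = TRUE, stringsAsFactors = FALSE))
    rows[[p]] <- les
  }
  list(lesions = do.call(rbind, rows),
       truth = data.frame(patient_id = sprintf("P%03d", seq_len(n_patients)),
                          category = truth, stringsAsFactors = FALSE))
}
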