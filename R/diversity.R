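#' Exclude normal-diploid and G2-like cells
#'
#' Excludes a cell when at least `purity_threshold` of its genome sits at
#' copy number 2 (a normal diploid contaminant: infiltrating lymphocyte or
#' normal epithelium) or at copy number 4 (a cell likely caught in G2, or a
#' doublet). A cancer cell with at least 5% of its genome altered away
#' from these states is retained.
#'
#' @param cn Integer copy-number matrix, bins x cells.
#' @param purity_threshold Fraction of the genome at the flat state that
#'   triggers exclusion (default 0.95, i.e. the "<5% altered" rule).
#' @return A list: `retained` (column-subset matrix) and `excluded`
#'   (data frame `cell_id, reason`).
#' @export
filter_normal_cells <- function(cn, purity_threshold = 0.95) {
  cn <- as_cell_matrix(cn)
  frac2 <- colMeans(cn == 2L)
  frac4 <- colMeans(cn == 4L)
  reason <- ifelse(frac2 >= purity_threshold, "normal_diploid",
            ifelse(frac4 >= purity_threshold, "g2_tetraploid", NA_character_))
  keep <- is.na(reason)
  list(retained = cn[, keep, drop = FALSE],
       excluded = data.frame(cell_id = colnames(cn)[!keep],
                             reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Exclude cells with noisy copy-number profiles
#'
#' Noisy single-cell profiles (S-phase cells with actively replicating DNA,
#' low-coverage cells, doublets) carry dense copy-number breakpoints that
#' no other cell of the same tumor shares. For each cell, the fraction of
#' its features — SCNA breakpoints (bin boundaries where the copy number
#' changes, matched in other cells by position within a +/-1 bin tolerance
#' and by the direction of the copy-number step) and
#' whole-chromosome aberrations (a chromosome uniformly away from the
#' cell's modal copy number) — that is present in at least one other cell
#' of the tumor is computed, and the cell is excluded when the shared
#' fraction falls below `share_threshold`. Cells with no features at all
#' are retained.
#'
#' @param cn Integer copy-number matrix, bins x cells (one tumor).
#' @param chrom Per-bin chromosome labels.
#' @param share_threshold Minimum shared-feature fraction (default 1/3).
#' @param tol Breakpoint matching tolerance in bins.
#' @return A list: `retained`, `excluded` (with the shared fraction), and
#'   `share` (per-cell shared fraction, NA when a cell has no features).
#' @export
filter_noisy_cells <- function(cn, chrom, share_threshold = 0.33, tol = 1L) {
  cn <- as_cell_matrix(cn)
  stopifnot(length(chrom) == nrow(cn))
  if (ncol(cn) < 2L) {
    warning("single-cell tumor: noisy-cell filter is a no-op")
    return(list(retained = cn,
                excluded = data.frame(cell_id = character(0),
                                      reason = character(0),
                                      share = numeric(0)),
                share = stats::setNames(NA_real_, colnames(cn))))
  }
  feats <- lapply(seq_len(ncol(cn)), function(j) cell_features(cn[, j], chrom))
  share <- vapply(seq_len(ncol(cn)), function(j) {
    f <- feats[[j]]
    n_feat <- nrow(f$bp) + length(f$wc)
    if (n_feat == 0L) return(NA_real_)
    others <- feats[-j]
    bp_hit <- if (nrow(f$bp)) vapply(seq_len(nrow(f$bp)), function(i)
      any(vapply(others, function(o)
        any(o$bp$chrom == f$bp$chrom[i] &
              abs(o$bp$pos - f$bp$pos[i]) <= tol &
              o$bp$sign == f$bp$sign[i]), TRUE)), TRUE) else logical(0)
    wc_hit <- vapply(f$wc, function(w)
      any(vapply(others, function(o) w %in% o$wc, TRUE)), TRUE)
    (sum(bp_hit) + sum(wc_hit)) / n_feat
  }, 0)
  keep <- is.na(share) | share >= share_threshold
  list(retained = cn[, keep, drop = FALSE],
       excluded = data.frame(cell_id = colnames(cn)[!keep],
                             reason = rep("noisy", sum(!keep)),
                             share = unname(share[!keep]),
                             stringsAsFactors = FALSE),
       share = stats::setNames(share, colnames(cn)))
}

# breakpoints (within-chromosome CN changes, with the direction of the
# step: sharing an SCNA breakpoint means sharing the same transition) and
# whole-chromosome aberrations of one profile
cell_features <- function(profile, chrom) {
  bp_chrom <- character(0); bp_pos <- integer(0); bp_sign <- integer(0)
  wc <- character(0)
  mode_cn <- as.integer(names(which.max(table(profile))))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    x <- profile[idx]
    dd <- diff(x)
    d <- which(dd != 0L)
    if (length(d)) {
      bp_chrom <- c(bp_chrom, rep(ch, length(d)))
      bp_pos <- c(bp_pos, d)
      bp_sign <- c(bp_sign, sign(dd[d]))
    } else if (x[1] != mode_cn) {
      wc <- c(wc, paste0(ch, ":", if (x[1] > mode_cn) "gain" else "loss"))
    }
  }
  list(bp = data.frame(chrom = bp_chrom, pos = bp_pos, sign = bp_sign,
                       stringsAsFactors = FALSE),
       wc = wc)
}

#' Pairwise copy-number diversity between cells
#'
#' For every pair of cells (optionally restricted to pairs from the same
#' FACS ploidy group), computes the fraction of the genome at which the two
#' profiles carry different copy numbers — the number of co-unmasked bins
#' with unequal CN divided by the number of co-unmasked bins. The same
#' operation measures clone-to-clone diversity when the columns are
#' subclone call tracks rather than single cells.
#'
#' @param cn Copy-number matrix, bins x cells; `NA` marks masked bins.
#' @param ploidy_group Optional per-cell group labels; when given,
#'   cross-group pairs are `NA` in the matrix and excluded from the mean.
#' @return A list of class `diversity_result`: `matrix` (symmetric pairwise
#'   fractions, zero diagonal) and `mean_diversity` (mean over compared
#'   pairs).
#' @export
pairwise_diversity <- function(cn, ploidy_group = NULL) {
  cn <- as_cell_matrix(cn)
  n <- ncol(cn)
  if (n < 2L) stop("need >= 2 cells for pairwise diversity")
  m <- matrix(NA_real_, n, n, dimnames = list(colnames(cn), colnames(cn)))
  diag(m) <- 0
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    if (!is.null(ploidy_group) && ploidy_group[i] != ploidy_group[j]) next
    ok <- !is.na(cn[, i]) & !is.na(cn[, j])
    if (!any(ok)) stop("cells ", i, " and ", j, " share no unmasked bins")
    m[i, j] <- m[j, i] <- mean(cn[ok, i] != cn[ok, j])
  }
  vals <- m[upper.tri(m)]
  if (all(is.na(vals))) stop("no valid cell pairs to compare")
  structure(list(matrix = m, mean_diversity = mean(vals, na.rm = TRUE)),
            class = "diversity_result")
}

#' Shannon evenness of clone proportions
#'
#' Groups cells into clones and measures how evenly the tumor's cells are
#' spread across them: with clone proportions `p_i` over `k` clones, the
#' Shannon entropy `H = -sum(p_i log p_i)` is normalized by its maximum
#' `log(k)`. Evenness lies in `[0, 1]` and is defined as 0 for a
#' single-clone tumor (no heterogeneity). By default cells are assigned to
#' the same clone when their profiles are identical after light median
#' smoothing (window of 3 bins), which absorbs isolated single-bin calls.
#'
#' @param cn Integer copy-number matrix, bins x cells (one tumor).
#' @param smooth Median-smooth profiles (window 3) before grouping.
#' @return A list: `evenness`, `n_clones`, `clone` (per-cell clone id),
#'   `proportions`.
#' @examples
#' shannon_evenness(cbind(a = rep(2, 30), b = rep(2, 30),
#'                        c = c(rep(3, 15), rep(2, 15))))
#' @export
shannon_evenness <- function(cn, smooth = TRUE) {
  cn <- as_cell_matrix(cn)
  prof <- if (smooth && nrow(cn) >= 3L)
    apply(cn, 2, function(x) stats::runmed(x, 3L)) else cn
  key <- apply(prof, 2, paste, collapse = ",")
  clone <- match(key, unique(key))
  p <- as.vector(table(clone)) / length(clone)
  k <- length(p)
  H <- -sum(p * log(p))
  list(evenness = if (k >= 2L) H / log(k) else 0,
       n_clones = k,
       clone = stats::setNames(clone, colnames(cn)),
       proportions = p)
}

#' Weighted genome instability index
#'
#' wGII of a copy-number profile relative to a ploidy: for each chromosome,
#' the fraction of its (unmasked) bins whose copy number differs from
#' `round(ploidy)`; wGII is the unweighted mean of these per-chromosome
#' fractions, so every chromosome contributes equally regardless of its
#' length. Chromosomes with all bins masked are excluded from the mean.
#'
#' @param profile Integer copy-number vector (NA = masked).
#' @param chrom Per-bin chromosome labels.
#' @param ploidy Reference ploidy (> 0); the comparison state is
#'   `round(ploidy)`.
#' @return A number in `[0, 1]`.
#' @export
wgii <- function(profile, chrom, ploidy) {
  stopifnot(length(profile) == length(chrom))
  if (ploidy <= 0) stop("ploidy must be > 0")
  ref <- round(ploidy)
  fr <- vapply(unique(chrom), function(ch) {
    x <- profile[chrom == ch]
    x <- x[!is.na(x)]
    if (!length(x)) NA_real_ else mean(x != ref)
  }, 0)
  mean(fr, na.rm = TRUE)
}

#' Per-cell ploidy and whole-genome-doubling flag
#'
#' Ploidy is the mean copy number over unmasked bins; a cell is flagged as
#' whole-genome doubled when its ploidy reaches `wgd_threshold` (default
#' 3.0: a doubled diploid genome that has since lost material still sits
#' well above 3, while an unduplicated near-diploid genome sits below).
#'
#' @param profile Integer copy-number vector (NA = masked).
#' @param wgd_threshold Mean-CN cutoff for calling WGD.
#' @return A list: `ploidy`, `wgd`.
#' @export
ploidy_and_wgd <- function(profile, wgd_threshold = 3.0) {
  x <- profile[!is.na(profile)]
  if (!length(x)) stop("profile has no unmasked bins")
  p <- mean(x)
  list(ploidy = p, wgd = p >= wgd_threshold)
}

#' Compare a per-tumor metric between groups
#'
#' Two-sided Mann-Whitney comparisons of a metric (evenness, wGII, mean
#' pairwise diversity, ...) between every pair of groups.
#'
#' @param values Numeric metric values (one per tumor or cell).
#' @param groups Group label per value.
#' @return A list: `summary` (n and median per group) and `tests` (a
#'   [test_result][mann_whitney_u] per group pair).
#' @export
group_compare <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need >= 2 groups")
  if (any(!table(groups) > 0L)) stop("empty group")
  summary <- data.frame(
    group = lv,
    n = vapply(lv, function(g) sum(groups == g), 0L),
    median = vapply(lv, function(g) stats::median(values[groups == g]), 0),
    row.names = NULL, stringsAsFactors = FALSE)
  tests <- list()
  for (i in seq_len(length(lv) - 1L)) for (j in seq(i + 1L, length(lv)))
    tests[[paste(lv[i], lv[j], sep = "_vs_")]] <-
      mann_whitney_u(values[groups == lv[i]], values[groups == lv[j]])
  list(summary = summary, tests = tests)
}

as_cell_matrix <- function(cn) {
  cn <- as.matrix(cn)
  if (is.null(colnames(cn)))
    colnames(cn) <- sprintf("cell%03d", seq_len(ncol(cn)))
  if (any(cn[!is.na(cn)] < 0)) stop("copy numbers must be >= 0")
  cn
}
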