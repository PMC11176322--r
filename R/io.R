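#' Read and write the pipeline's delimited-text formats
#'
#' Plain tab-separated representations of the pipeline's inputs and
#' outputs: BED-like bin counts (`chrom, start, end, count`), SNP
#' allele-count tables (`chrom, pos, ref_count, alt_count`), copy-number
#' matrices (first three columns the bin grid, one column per cell/tumor),
#' long-format lesion tables (`patient_id, lesion_id, timepoint,
#' diameter_mm, is_new` with timepoints `baseline` and `followup`), and
#' per-bin call tracks (`chrom, start, end, call, z, p`).
#'
#' @param path File path.
#' @param x Object to write (see each writer).
#' @return Readers return the parsed object; writers return `path`
#'   invisibly.
#' @name scnamix_io
NULL

#' @rdname scnamix_io
#' @export
read_bin_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "start", "end", "count") %in% names(df)))
  df
}

#' @rdname scnamix_io
#' @export
write_bin_counts <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname scnamix_io
#' @export
read_snp_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref_count", "alt_count") %in% names(df)))
  df
}

#' @rdname scnamix_io
#' @export
write_snp_table <- function(x, path) {
  utils::write.table(x[, c("chrom", "pos", "ref_count", "alt_count")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname scnamix_io
#' @param bins Bin grid to attach as the coordinate columns.
#' @export
write_cn_matrix <- function(x, bins, path) {
  stopifnot(nrow(x) == nrow(bins))
  utils::write.table(cbind(bins[, c("chrom", "start", "end")], x), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname scnamix_io
#' @export
read_cn_matrix <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("chrom", "start", "end") %in% names(df)[1:3]))
  cn <- as.matrix(df[, -(1:3), drop = FALSE])
  list(cn = cn, bins = df[, 1:3])
}

#' @rdname scnamix_io
#' @export
write_lesion_table <- function(x, path) {
  long <- rbind(
    data.frame(patient_id = x$patient_id, lesion_id = x$lesion_id,
               timepoint = "baseline", diameter_mm = x$baseline_diameter,
               is_new = x$is_new, stringsAsFactors = FALSE),
    data.frame(patient_id = x$patient_id, lesion_id = x$lesion_id,
               timepoint = "followup", diameter_mm = x$followup_diameter,
               is_new = x$is_new, stringsAsFactors = FALSE))
  long <- long[order(long$patient_id, long$lesion_id, long$timepoint), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname scnamix_io
#' @export
read_lesion_table <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("patient_id", "lesion_id", "timepoint", "diameter_mm",
                  "is_new") %in% names(long)))
  base <- long[long$timepoint == "baseline", ]
  fup <- long[long$timepoint == "followup", ]
  m <- match(fup$lesion_id, base$lesion_id)
  if (anyNA(m)) stop("follow-up lesion(s) without a baseline row")
  data.frame(patient_id = fup$patient_id, lesion_id = fup$lesion_id,
             baseline_diameter = base$diameter_mm[m],
             followup_diameter = fup$diameter_mm,
             is_new = as.logical(fup$is_new), stringsAsFactors = FALSE)
}

#' @rdname scnamix_io
#' @export
write_call_track <- function(x, path) {
  utils::write.table(x[, c("chrom", "start", "end", "call", "z", "p")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
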