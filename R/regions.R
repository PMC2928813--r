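# Interval bookkeeping shared by both scans: merging, sizing,
# intersection with known loci, and cross-method consensus.
# Coordinates are 1-based inclusive throughout; BED input is 0-based
# half-open and converted on read.

#' Build an interval table
#'
#' @param chrom,start_bp,end_bp vectors defining 1-based closed intervals.
#' @param label optional labels.
#' @return data.frame with columns `chrom`, `start_bp`, `end_bp`, `label`.
#' @export
genomic_intervals <- function(chrom, start_bp, end_bp, label = NA_character_) {
  if (any(start_bp > end_bp)) {
    az_stop("interval start exceeds end", "autozyg_validation_error")
  }
  data.frame(chrom = as.character(chrom), start_bp = start_bp,
             end_bp = end_bp, label = rep_len(label, length(chrom)),
             stringsAsFactors = FALSE)
}

intervals_to_granges <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start_bp, x$end_bp))
}

granges_to_intervals <- function(gr, label = NA_character_) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start_bp = GenomicRanges::start(gr),
                   end_bp = GenomicRanges::end(gr),
                   label = rep_len(label, length(gr)),
                   stringsAsFactors = FALSE)
  df <- df[order(chrom_rank(df$chrom), df$start_bp), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Merge intervals that overlap or touch
#'
#' Intervals that overlap, share a boundary coordinate, or are directly
#' adjacent (no intervening base) are merged; intervals separated by at
#' least one base are not. The output is sorted, pairwise disjoint and
#' non-adjacent, and the operation is idempotent and order-invariant.
#'
#' @param intervals data.frame with `chrom`, `start_bp`, `end_bp`.
#' @return merged interval data.frame.
#' @export
merge_touching <- function(intervals) {
  if (nrow(intervals) == 0) return(genomic_intervals(character(), numeric(), numeric()))
  gr <- GenomicRanges::reduce(intervals_to_granges(intervals))
  granges_to_intervals(gr)
}

#' Interval span in Mbp
#'
#' Reports `(end_bp - start_bp) / 1e6` rounded half-up to `decimals`
#' places — the simple coordinate difference used for headline interval
#' sizes. Set `inclusive = TRUE` for the `+1` (inclusive base count)
#' variant; at two decimals the two conventions agree for Mbp-scale
#' intervals.
#'
#' @param interval data.frame row(s) with `start_bp`, `end_bp`.
#' @param decimals number of decimal places.
#' @param inclusive add 1 bp (count bases rather than the coordinate
#'   difference).
#' @return numeric vector of spans in Mbp.
#' @export
span_mbp <- function(interval, decimals = 2, inclusive = FALSE) {
  round_half_up((interval$end_bp - interval$start_bp + inclusive) / 1e6, decimals)
}

#' Cross-method consensus of candidate regions
#'
#' Intersects HH-scan regions with merged IBS-run regions. Portions of
#' the genome supported by only one method are reported with a
#' single-method flag rather than dropped, since a region flagged by one
#' scan but not homozygous-IBS in all affecteds (or vice versa) is
#' exactly the pattern that disqualified secondary candidates.
#'
#' @param rcchs HH regions (data.frame with `chrom`, `start_bp`, `end_bp`).
#' @param merged_runs merged IBS regions (same columns).
#' @return data.frame of intervals with a `support` column:
#'   `"BOTH"`, `"HH_ONLY"` or `"IBS_ONLY"`; sorted by position.
#' @export
consensus <- function(rcchs, merged_runs) {
  hh <- intervals_to_granges(rcchs)
  ibs <- intervals_to_granges(merged_runs)
  sl <- union(GenomeInfoDb::seqlevels(hh), GenomeInfoDb::seqlevels(ibs))
  GenomeInfoDb::seqlevels(hh) <- sl
  GenomeInfoDb::seqlevels(ibs) <- sl
  both <- GenomicRanges::intersect(hh, ibs)
  hh_only <- GenomicRanges::setdiff(hh, ibs)
  ibs_only <- GenomicRanges::setdiff(ibs, hh)
  res <- rbind(granges_to_intervals(both, "BOTH"),
               granges_to_intervals(hh_only, "HH_ONLY"),
               granges_to_intervals(ibs_only, "IBS_ONLY"))
  names(res)[names(res) == "label"] <- "support"
  res <- res[order(chrom_rank(res$chrom), res$start_bp, res$support), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Read known disease loci from a BED file
#'
#' BED intervals (0-based, half-open) are converted to the package's
#' 1-based closed convention. Unnamed records receive `locus<N>` names.
#'
#' @param path path to a BED file (3+ columns).
#' @return data.frame with `name`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_known_loci <- function(path) {
  if (!file.exists(path)) az_stop(sprintf("BED file not found: %s", path), "autozyg_io_error")
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || all(is.na(nm))) nm <- sprintf("locus%d", seq_along(gr))
  data.frame(name = nm,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),  # rtracklayer converts to 1-based closed
             end_bp = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Write intervals as a BED file
#'
#' Converts from 1-based closed back to BED's 0-based half-open
#' coordinates, so [read_known_loci()] round-trips.
#'
#' @param intervals data.frame with `chrom`, `start_bp`, `end_bp` and an
#'   optional `name` (or `label`) column.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_known_loci <- function(intervals, path) {
  nm <- intervals$name %||% intervals$label %||% sprintf("locus%d", seq_len(nrow(intervals)))
  lines <- sprintf("%s\t%d\t%d\t%s", intervals$chrom,
                   as.integer(intervals$start_bp) - 1L,
                   as.integer(intervals$end_bp), nm)
  writeLines(lines, path)
  invisible(path)
}
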