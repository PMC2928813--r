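# Repair of centimorgan positions in SNP-array annotation tables.
#
# Array annotation files routinely carry genetic distances that are empty,
# zero, or locally non-monotone. Downstream genetic-length arithmetic
# (e.g. the 3 cM cutoff of the HH scan) needs a clean non-decreasing map,
# so invalid values are flagged and replaced by linear interpolation in
# physical coordinates between the nearest valid flanking markers.

# Membership in one longest non-decreasing subsequence of v. Among
# equally long repairs the chain ending at the smallest value is chosen
# and reconstruction walks right-to-left picking the earliest feasible
# predecessor: upward spikes are flagged rather than the trend around
# them, and a later dip is flagged, not the value it dips below.
lnds_keep <- function(v) {
  n <- length(v)
  if (n <= 1) return(rep(TRUE, n))
  len <- integer(n)
  tails <- numeric(0)
  for (i in seq_len(n)) {
    k <- findInterval(v[i], tails) + 1L
    len[i] <- k
    if (k > length(tails)) tails <- c(tails, v[i]) else tails[k] <- v[i]
  }
  L <- max(len)
  keep <- logical(n)
  ends <- which(len == L)
  idx <- ends[which.min(v[ends])]
  keep[idx] <- TRUE
  if (L > 1) {
    for (k in seq(L - 1, 1)) {
      cand <- which(len == k)
      cand <- cand[cand < idx & v[cand] <= v[idx]]
      idx <- cand[1]
      keep[idx] <- TRUE
    }
  }
  keep
}

check_map_sorted <- function(markers) {
  o <- order(chrom_rank(markers$chrom), markers$pos_bp)
  if (!identical(o, seq_len(nrow(markers)))) {
    az_stop("marker table is not sorted by (chromosome, bp position)",
            "autozyg_ordering_error")
  }
}

#' Flag invalid centimorgan values in a marker table
#'
#' A centimorgan value is invalid when it is absent, exactly zero (except
#' at the first marker of a chromosome, which is kept as a valid
#' chromosome-start anchor), or off the longest non-decreasing subsequence
#' of the remaining valid values on its chromosome — the minimal set of
#' repairs that restores monotonicity.
#'
#' @param markers marker data.frame (`id`, `chrom`, `pos_bp`, `cm`), sorted
#'   by (chromosome, position).
#' @return the same data.frame with a logical `cm_valid` column.
#' @export
classify_invalid <- function(markers) {
  check_map_sorted(markers)
  markers$cm_valid <- FALSE
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    cm <- markers$cm[idx]
    valid <- !is.na(cm)
    zero <- valid & cm == 0
    zero[1] <- FALSE  # chromosome-start anchor may legitimately be 0
    valid[zero] <- FALSE
    if (any(valid)) valid[valid] <- lnds_keep(cm[valid])
    markers$cm_valid[idx] <- valid
  }
  markers
}

#' Interpolate invalid centimorgan values from physical coordinates
#'
#' Each flagged marker receives the linear interpolation, in bp, between
#' the nearest valid flanking markers on its chromosome. Markers before
#' the first (after the last) valid marker receive the first (last) valid
#' value — constant extrapolation, which avoids negative map positions.
#' The repaired map is non-decreasing and the operation is idempotent.
#'
#' @param markers marker data.frame; if it lacks a `cm_valid` column,
#'   [classify_invalid()] is applied first.
#' @return the data.frame with `cm` repaired, plus logical columns
#'   `cm_valid` (all `TRUE` on output) and `cm_repaired` marking the
#'   markers whose value was replaced.
#' @export
interpolate_cm <- function(markers) {
  if (is.null(markers$cm_valid)) markers <- classify_invalid(markers)
  check_map_sorted(markers)
  markers$cm_repaired <- !markers$cm_valid
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    valid <- markers$cm_valid[idx]
    if (all(valid)) next
    if (sum(valid) < 2) {
      az_stop(sprintf("chromosome %s has fewer than two valid cM values; cannot interpolate", ch),
              "autozyg_interpolation_error")
    }
    fit <- stats::approx(x = markers$pos_bp[idx][valid],
                         y = markers$cm[idx][valid],
                         xout = markers$pos_bp[idx][!valid],
                         method = "linear", rule = 2, ties = "ordered")
    markers$cm[idx][!valid] <- fit$y
  }
  markers$cm_valid <- TRUE
  markers
}
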