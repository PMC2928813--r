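# Shared identical-by-state run-of-homozygosity scan.
#
# The unit of evidence is a maximal run of consecutive markers at which
# every affected sample is homozygous for the same allele. Long runs are
# occasionally interrupted by isolated heterozygous calls in single
# samples — false heterozygote genotype calls on an autozygous background
# — so neighbouring runs may be bridged across such markers. Missing
# calls break a run and never bridge: the interruption model is
# specifically miscalled heterozygotes, not missingness.

#' IBS run scan configuration
#'
#' @param min_run_snps minimum number of consecutive conforming markers
#'   for a reported run.
#' @param bridge_max_gap_snps maximum number of consecutive interrupting
#'   markers that [bridge_runs()] may jump.
#' @param bridge_max_carriers maximum number of affected samples allowed
#'   to be heterozygous at an interrupting marker for it to be bridgeable.
#' @param contrast_threshold fraction of region markers at which an
#'   unaffected sample must match the shared homozygous genotype for the
#'   region to be called non-segregating (see [contrast_unaffected()]).
#' @return a list of class `scan_config`.
#' @export
scan_config <- function(min_run_snps = 35L, bridge_max_gap_snps = 1L,
                        bridge_max_carriers = 1L, contrast_threshold = 0.95) {
  stopifnot(min_run_snps >= 1, bridge_max_gap_snps >= 0,
            bridge_max_carriers >= 0,
            contrast_threshold > 0, contrast_threshold <= 1)
  structure(list(min_run_snps = as.integer(min_run_snps),
                 bridge_max_gap_snps = as.integer(bridge_max_gap_snps),
                 bridge_max_carriers = as.integer(bridge_max_carriers),
                 contrast_threshold = contrast_threshold),
            class = "scan_config")
}

# per-marker predicate: every affected homozygous, all for the same allele
conforming_alleles <- function(panel, affected_ids) {
  j <- match(affected_ids, panel$samples$id)
  if (anyNA(j)) {
    az_stop(sprintf("unknown sample '%s'", affected_ids[is.na(j)][1]),
            "autozyg_lookup_error")
  }
  calls <- panel$calls[, j, drop = FALSE]
  k <- length(j)
  all_a <- rowSums(calls == "AA" & !is.na(calls)) == k
  all_b <- rowSums(calls == "BB" & !is.na(calls)) == k
  ifelse(all_a, "A", ifelse(all_b, "B", NA_character_))
}

#' Maximal runs of shared homozygosity, identical by state
#'
#' Returns every maximal run of consecutive markers (within one
#' chromosome) at which all affected samples are homozygous and carry the
#' identical allele, keeping runs of at least `min_run_snps` markers.
#' Interval sizes use the 1-based inclusive convention
#' (`size_bp = end_bp - start_bp + 1`). Output is sorted by descending
#' SNP count, ties broken by (chromosome, start).
#'
#' @param panel a `genotype_panel`.
#' @param affected_ids ids of the affected samples (at least one).
#' @param config a [scan_config()].
#' @return data.frame of runs with marker/bp boundaries, `n_snps`,
#'   `size_bp` and a `shared_allele` list-column (per-marker allele
#'   vector); attributes record the panel signature, affected ids and
#'   configuration.
#' @export
shared_ibs_runs <- function(panel, affected_ids, config = scan_config()) {
  if (length(affected_ids) < 1) {
    az_stop("at least one affected sample id is required", "autozyg_validation_error")
  }
  allele <- conforming_alleles(panel, affected_ids)
  m <- panel$markers
  out <- list()
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    conf <- !is.na(allele[idx])
    r <- rle(conf)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (s in which(r$values & r$lengths >= config$min_run_snps)) {
      gi <- idx[starts[s]:ends[s]]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch,
        start_idx = gi[1], end_idx = gi[length(gi)],
        start_snp = m$id[gi[1]], end_snp = m$id[gi[length(gi)]],
        start_bp = m$pos_bp[gi[1]], end_bp = m$pos_bp[gi[length(gi)]],
        n_snps = length(gi),
        size_bp = m$pos_bp[gi[length(gi)]] - m$pos_bp[gi[1]] + 1,
        stringsAsFactors = FALSE)
      out[[length(out)]]$shared_allele <- list(allele[gi])
    }
  }
  res <- if (length(out)) do.call(rbind, out) else empty_run_table()
  res <- res[order(-res$n_snps, chrom_rank(res$chrom), res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "panel_signature") <- panel_signature(panel)
  attr(res, "affected_ids") <- affected_ids
  attr(res, "config") <- config
  class(res) <- c("shared_run_table", class(res))
  res
}

empty_run_table <- function() {
  df <- data.frame(chrom = character(), start_idx = integer(),
                   end_idx = integer(), start_snp = character(),
                   end_snp = character(), start_bp = numeric(),
                   end_bp = numeric(), n_snps = integer(),
                   size_bp = numeric(), stringsAsFactors = FALSE)
  df$shared_allele <- list()
  df
}

#' Physical size of a run or interval (inclusive convention)
#'
#' `end - start + 1`: a single-marker interval has size 1.
#'
#' @param run data.frame with `start_bp` and `end_bp` columns (vectorised).
#' @return numeric vector of sizes in bp.
#' @export
run_size_bp <- function(run) {
  run$end_bp - run$start_bp + 1
}

# Can the gap markers (global indices) be bridged under the config?
# TRUE only when every gap marker fails the run predicate solely because
# <= max_carriers affecteds are heterozygous: no missing call, and all
# homozygous calls agree on one allele.
gap_bridgeable <- function(panel, affected_ids, gap_idx, config) {
  if (length(gap_idx) == 0) return(TRUE)
  if (length(gap_idx) > config$bridge_max_gap_snps) return(FALSE)
  j <- match(affected_ids, panel$samples$id)
  calls <- panel$calls[gap_idx, j, drop = FALSE]
  if (anyNA(calls)) return(FALSE)
  n_het <- rowSums(calls == "AB")
  if (any(n_het > config$bridge_max_carriers)) return(FALSE)
  has_a <- rowSums(calls == "AA") > 0
  has_b <- rowSums(calls == "BB") > 0
  !any(has_a & has_b)
}

#' Bridge runs across isolated false-heterozygote interruptions
#'
#' Two runs on the same chromosome are merged when they are separated by
#' at most `bridge_max_gap_snps` consecutive markers, each of which is
#' non-conforming only because at most `bridge_max_carriers` affected
#' samples are heterozygous there. An allele conflict (one affected
#' A-homozygous, another B-homozygous) or a missing call never bridges.
#' Merging is transitive, so a chain of singleton interruptions collapses
#' into one region.
#'
#' @param runs output of [shared_ibs_runs()] computed on `panel`.
#' @param panel the same `genotype_panel`.
#' @param affected_ids affected sample ids; defaults to those recorded on
#'   `runs`.
#' @param config a [scan_config()]; defaults to the one recorded on `runs`.
#' @return data.frame of merged regions with total (unique) SNP count,
#'   bp span, the number of source runs and of bridged markers.
#' @export
bridge_runs <- function(runs, panel,
                        affected_ids = attr(runs, "affected_ids"),
                        config = attr(runs, "config") %||% scan_config()) {
  check_signature(runs, panel, "run table")
  force(affected_ids); force(config)  # defaults read attrs of `runs` before it is re-sorted
  o <- order(chrom_rank(runs$chrom), runs$start_bp)
  runs <- runs[o, , drop = FALSE]
  n <- nrow(runs)
  out <- list()
  i <- 1L
  while (i <= n) {
    start_i <- i
    n_bridged <- 0L
    while (i < n && runs$chrom[i + 1] == runs$chrom[i]) {
      gap <- seq.int(runs$end_idx[i] + 1L, length.out = runs$start_idx[i + 1] - runs$end_idx[i] - 1L)
      if (!gap_bridgeable(panel, affected_ids, gap, config)) break
      n_bridged <- n_bridged + length(gap)
      i <- i + 1L
    }
    first <- runs[start_i, ]; last <- runs[i, ]
    out[[length(out) + 1]] <- data.frame(
      chrom = first$chrom,
      start_idx = first$start_idx, end_idx = last$end_idx,
      start_snp = first$start_snp, end_snp = last$end_snp,
      start_bp = first$start_bp, end_bp = last$end_bp,
      n_snps = last$end_idx - first$start_idx + 1L,
      size_bp = last$end_bp - first$start_bp + 1,
      n_runs = i - start_i + 1L,
      n_bridged_snps = n_bridged,
      stringsAsFactors = FALSE)
    i <- i + 1L
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = character(), start_idx = integer(), end_idx = integer(),
    start_snp = character(), end_snp = character(),
    start_bp = numeric(), end_bp = numeric(), n_snps = integer(),
    size_bp = numeric(), n_runs = integer(), n_bridged_snps = integer(),
    stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "panel_signature") <- panel_signature(panel)
  attr(res, "affected_ids") <- affected_ids
  attr(res, "config") <- config
  class(res) <- c("merged_region_table", class(res))
  res
}

#' Contrast candidate regions against unaffected samples
#'
#' For each region, every unaffected sample is scored by the fraction of
#' region markers at which it is homozygous for the affecteds' shared
#' allele (markers without a unanimous homozygous consensus among
#' affecteds are skipped). A region where any unaffected reaches
#' `contrast_threshold` is flagged `NOT_SEGREGATING`: the haplotype is
#' also carried homozygously outside the affected set.
#'
#' @param regions merged regions from [bridge_runs()] (or runs).
#' @param panel the `genotype_panel` the regions came from.
#' @param unaffected_ids ids of unaffected samples (may be empty, in which
#'   case regions pass through unflagged).
#' @param affected_ids defaults to those recorded on `regions`.
#' @param threshold match-fraction threshold; defaults to the config on
#'   `regions`.
#' @return `regions` with added columns `not_segregating` and
#'   `matching_unaffected`; the per-sample score table is attached as
#'   attribute `"contrast"`.
#' @export
contrast_unaffected <- function(regions, panel, unaffected_ids,
                                affected_ids = attr(regions, "affected_ids"),
                                threshold = NULL) {
  check_signature(regions, panel, "region table")
  if (is.null(threshold)) {
    cfg <- attr(regions, "config")
    threshold <- if (!is.null(cfg)) cfg$contrast_threshold else 0.95
  }
  regions$not_segregating <- logical(nrow(regions))
  regions$matching_unaffected <- rep(NA_character_, nrow(regions))
  if (!length(unaffected_ids) || nrow(regions) == 0) return(regions)
  ju <- match(unaffected_ids, panel$samples$id)
  if (anyNA(ju)) {
    az_stop(sprintf("unknown sample '%s'", unaffected_ids[is.na(ju)][1]),
            "autozyg_lookup_error")
  }
  ja <- match(affected_ids, panel$samples$id)
  detail <- list()
  for (r in seq_len(nrow(regions))) {
    idx <- regions$start_idx[r]:regions$end_idx[r]
    aff <- panel$calls[idx, ja, drop = FALSE]
    # unanimous homozygous consensus among affecteds at each marker
    nAA <- rowSums(aff == "AA" & !is.na(aff))
    nBB <- rowSums(aff == "BB" & !is.na(aff))
    consensus <- ifelse(nAA > 0 & nBB == 0, "AA",
                        ifelse(nBB > 0 & nAA == 0, "BB", NA_character_))
    informative <- !is.na(consensus)
    for (u in seq_along(unaffected_ids)) {
      uc <- panel$calls[idx, ju[u]]
      frac <- if (any(informative)) {
        mean(!is.na(uc[informative]) & uc[informative] == consensus[informative])
      } else NA_real_
      matches <- !is.na(frac) && frac >= threshold
      detail[[length(detail) + 1]] <- data.frame(
        region = r, sample = unaffected_ids[u],
        match_fraction = frac, matches = matches,
        stringsAsFactors = FALSE)
      if (matches) {
        regions$not_segregating[r] <- TRUE
        regions$matching_unaffected[r] <- paste(
          stats::na.omit(c(regions$matching_unaffected[r], unaffected_ids[u])),
          collapse = ",")
      }
    }
  }
  attr(regions, "contrast") <- do.call(rbind, detail)
  regions
}

#' Rank candidate regions by SNP support
#'
#' Sorts regions by descending total SNP count (ties by chromosome then
#' start) and reports, for each region, the ratio of its SNP count to the
#' next-ranked region's — the outlier diagnostic that separates a single
#' autozygous candidate from the background of chance runs. The
#' bottom-ranked (or a lone) region gets ratio `Inf`.
#'
#' @param regions data.frame with `n_snps`, `chrom`, `start_bp`.
#' @return the regions sorted, with columns `rank` and `ratio_to_next`.
#' @export
rank_candidates <- function(regions) {
  if (nrow(regions) == 0) {
    regions$rank <- integer(0)
    regions$ratio_to_next <- numeric(0)
    return(regions)
  }
  o <- order(-regions$n_snps, chrom_rank(regions$chrom), regions$start_bp)
  res <- regions[o, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  nxt <- c(res$n_snps[-1], NA)
  res$ratio_to_next <- ifelse(is.na(nxt), Inf, res$n_snps / nxt)
  rownames(res) <- NULL
  for (a in c("panel_signature", "affected_ids", "config", "contrast")) {
    attr(res, a) <- attr(regions, a)
  }
  res
}
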