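# Homozygous-haplotype (HH) linkage scan.
#
# The HH method works on the subset of completely homozygous markers in
# each affected individual and flags regions free of allele-discordant
# homozygous markers (one affected A-homozygous, another B-homozygous).
# Stretches are additionally split across large physical gaps between
# informative markers (centromere-like gaps) and reported when their
# genetic length reaches a cutoff. Unaffected samples play no role in
# this scan; they enter only in the identical-by-state run scan.

#' HH scan configuration
#'
#' @param cutoff_cm minimum genetic length (cM) for a reported region.
#' @param largegap_bp maximum physical distance (bp) between consecutive
#'   informative markers before a region is split. The default mirrors the
#'   setting used for ~610k Illumina panels, where 400,000 bp accommodates
#'   non-centromeric gaps as well.
#' @param min_informative_snps minimum number of informative markers a
#'   region must contain (0 imposes no such minimum).
#' @return a list of class `hh_config`.
#' @export
hh_config <- function(cutoff_cm = 3.0, largegap_bp = 400000L,
                      min_informative_snps = 0L) {
  stopifnot(cutoff_cm > 0, largegap_bp > 0, min_informative_snps >= 0)
  structure(list(cutoff_cm = cutoff_cm, largegap_bp = largegap_bp,
                 min_informative_snps = min_informative_snps),
            class = "hh_config")
}

#' Homozygosity haplotype of one sample
#'
#' Extracts exactly the markers at which the sample's call is homozygous
#' (AA or BB), with the carried allele; heterozygous and missing calls are
#' excluded.
#'
#' @param panel a `genotype_panel`.
#' @param sample_id a sample id present in the panel.
#' @return data.frame with columns `marker_idx` (row index into the panel
#'   marker table), `marker_id` and `allele` ("A" or "B").
#' @export
homozygous_subset <- function(panel, sample_id) {
  j <- match(sample_id, panel$samples$id)
  if (is.na(j)) az_stop(sprintf("unknown sample '%s'", sample_id), "autozyg_lookup_error")
  g <- panel$calls[, j]
  keep <- which(!is.na(g) & g != "AB")
  data.frame(marker_idx = keep,
             marker_id = panel$markers$id[keep],
             allele = ifelse(g[keep] == "AA", "A", "B"),
             stringsAsFactors = FALSE)
}

# allele matrix over the given samples: "A"/"B" where homozygous, NA else
hh_allele_matrix <- function(panel, sample_ids) {
  j <- match(sample_ids, panel$samples$id)
  if (anyNA(j)) {
    az_stop(sprintf("unknown sample '%s'", sample_ids[is.na(j)][1]),
            "autozyg_lookup_error")
  }
  calls <- panel$calls[, j, drop = FALSE]
  al <- matrix(NA_character_, nrow(calls), ncol(calls),
               dimnames = list(rownames(calls), sample_ids))
  al[calls == "AA" & !is.na(calls)] <- "A"
  al[calls == "BB" & !is.na(calls)] <- "B"
  al
}

#' Discordance points among homozygosity haplotypes
#'
#' A marker is a discordance point when at least two of the supplied
#' haplotypes are homozygous for different alleles there (one A-homozygote
#' and one B-homozygote). Heterozygous or missing calls are outside the
#' homozygosity haplotype and never create discordance.
#'
#' @param haps list of homozygosity haplotypes from [homozygous_subset()]
#'   (at least two).
#' @return sorted integer vector of discordant marker indices.
#' @export
find_discordance_points <- function(haps) {
  if (length(haps) < 2) {
    az_stop("at least two homozygosity haplotypes are required",
            "autozyg_validation_error")
  }
  a_idx <- unique(unlist(lapply(haps, function(h) h$marker_idx[h$allele == "A"])))
  b_idx <- unique(unlist(lapply(haps, function(h) h$marker_idx[h$allele == "B"])))
  sort(intersect(a_idx, b_idx))
}

#' Scan for regions of conserved homozygosity haplotype (RCHH)
#'
#' Candidate regions are maximal stretches of markers free of discordance
#' points among the affected samples, additionally split wherever two
#' consecutive informative markers (homozygous in at least one affected)
#' lie more than `largegap_bp` apart. Regions whose genetic length reaches
#' `cutoff_cm` are returned; boundaries are the outermost concordant
#' markers, so discordance points are excluded from every region.
#'
#' @param panel a `genotype_panel` whose markers carry valid, non-missing
#'   cM positions (run [interpolate_cm()] first if needed).
#' @param affected_ids ids of at least two affected samples.
#' @param config an [hh_config()].
#' @return data.frame of regions (one per row) with marker/bp boundaries,
#'   `genetic_length_cm`, `n_informative_snps`, `n_snps` and
#'   `supporting_samples`; sorted by chromosome then start.
#' @export
shared_rcch <- function(panel, affected_ids, config = hh_config()) {
  if (length(affected_ids) < 2) {
    az_stop("HH scan needs at least two affected samples", "autozyg_validation_error")
  }
  m <- panel$markers
  if (anyNA(m$cm)) {
    az_stop("marker cM positions contain missing values; repair the genetic map with interpolate_cm() first",
            "autozyg_precondition_error")
  }
  for (ch in unique(m$chrom)) {
    if (is.unsorted(m$cm[m$chrom == ch])) {
      az_stop(sprintf("cM positions on chromosome %s are not non-decreasing; repair the genetic map with interpolate_cm() first", ch),
              "autozyg_precondition_error")
    }
  }
  al <- hh_allele_matrix(panel, affected_ids)
  has_a <- rowSums(al == "A", na.rm = TRUE) > 0
  has_b <- rowSums(al == "B", na.rm = TRUE) > 0
  discord <- has_a & has_b
  informative <- has_a | has_b

  out <- list()
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    n <- length(idx)
    # break after marker i when the next informative marker is too far
    # from the previous informative one (in bp)
    inf_local <- which(informative[idx])
    break_after <- logical(n)
    if (length(inf_local) >= 2) {
      gaps <- diff(m$pos_bp[idx][inf_local])
      big <- which(gaps > config$largegap_bp)
      break_after[inf_local[big]] <- TRUE
    }
    block <- rep(NA_integer_, n)
    cur <- 0L; open <- FALSE
    for (i in seq_len(n)) {
      if (discord[idx[i]]) { open <- FALSE; next }
      if (!open) { cur <- cur + 1L; open <- TRUE }
      block[i] <- cur
      if (break_after[i]) open <- FALSE
    }
    for (b in seq_len(cur)) {
      loc <- which(block == b)
      if (!length(loc)) next
      gi <- idx[loc]
      cm_len <- m$cm[gi[length(gi)]] - m$cm[gi[1]]
      n_inf <- sum(informative[gi])
      if (cm_len >= config$cutoff_cm && n_inf >= config$min_informative_snps) {
        out[[length(out) + 1]] <- data.frame(
          chrom = ch,
          start_marker = m$id[gi[1]], end_marker = m$id[gi[length(gi)]],
          start_bp = m$pos_bp[gi[1]], end_bp = m$pos_bp[gi[length(gi)]],
          start_idx = gi[1], end_idx = gi[length(gi)],
          genetic_length_cm = cm_len,
          n_informative_snps = n_inf,
          n_snps = length(gi),
          supporting_samples = paste(sort(affected_ids), collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else data.frame(
    chrom = character(), start_marker = character(), end_marker = character(),
    start_bp = numeric(), end_bp = numeric(),
    start_idx = integer(), end_idx = integer(),
    genetic_length_cm = numeric(), n_informative_snps = integer(),
    n_snps = integer(), supporting_samples = character(),
    stringsAsFactors = FALSE)
  res <- res[order(chrom_rank(res$chrom), res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "panel_signature") <- panel_signature(panel)
  attr(res, "config") <- config
  class(res) <- c("rcch_table", class(res))
  res
}

#' Test known disease loci against scan regions
#'
#' Each locus is reported `OVERLAPPED` when some candidate region
#' intersects it on the bp interval (closed at both ends, same chromosome)
#' and `EXCLUDED` otherwise. An empty region list excludes every locus.
#'
#' @param rcchs region data.frame with `chrom`, `start_bp`, `end_bp`
#'   (RCHHs from [shared_rcch()] or any interval table).
#' @param loci data.frame of known loci with `name`, `chrom`, `start_bp`,
#'   `end_bp` (see [read_known_loci()]).
#' @return data.frame with one row per locus: `name`, `chrom`,
#'   `start_bp`, `end_bp`, `verdict`, `overlapping_region`.
#' @export
test_known_loci <- function(rcchs, loci) {
  verdict <- rep("EXCLUDED", nrow(loci))
  overlap <- rep(NA_character_, nrow(loci))
  if (nrow(rcchs) > 0 && nrow(loci) > 0) {
    sl <- union(unique(rcchs$chrom), unique(loci$chrom))
    rg <- GenomicRanges::GRanges(factor(rcchs$chrom, levels = sl),
                                 IRanges::IRanges(rcchs$start_bp, rcchs$end_bp))
    lg <- GenomicRanges::GRanges(factor(loci$chrom, levels = sl),
                                 IRanges::IRanges(loci$start_bp, loci$end_bp))
    hits <- GenomicRanges::findOverlaps(lg, rg)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (i in unique(qh)) {
      verdict[i] <- "OVERLAPPED"
      js <- sh[qh == i]
      overlap[i] <- paste(sprintf("%s:%d-%d", rcchs$chrom[js],
                                  as.integer(rcchs$start_bp[js]),
                                  as.integer(rcchs$end_bp[js])),
                          collapse = ";")
    }
  }
  data.frame(name = loci$name, chrom = loci$chrom,
             start_bp = loci$start_bp, end_bp = loci$end_bp,
             verdict = verdict, overlapping_region = overlap,
             stringsAsFactors = FALSE)
}
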