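# Worked-example fixtures: reconstruction of candidate-region geometry
# from a published-style interval table. The packaged TSV holds the
# boundary coordinates and SNP counts of the shared-homozygosity
# intervals of a six-affected consanguineous CMT pedigree; the builders
# below synthesise genotype panels realising that geometry so the scans
# can be exercised end-to-end without any genotype deposit.

#' Load the packaged candidate-run interval table
#'
#' Columns: `snps`, `chrom`, `start_snp`, `end_snp`, `start_bp`,
#' `end_bp`, `size_bp`, `contiguous` (whether the row belongs to the
#' contiguous chromosome-9 candidate block).
#'
#' @return data.frame of 14 intervals.
#' @export
load_example_runs <- function() {
  path <- system.file("extdata", "candidate_runs.tsv", package = "autozyg")
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = c("integer", "character", "character",
                                   "character", "numeric", "numeric",
                                   "numeric", "character"))
}

example_samples <- function(n_affected = 6L) {
  data.frame(id = sprintf("P%d", seq_len(n_affected)),
             father_id = NA_character_, mother_id = NA_character_,
             sex = "unknown", status = "affected",
             stringsAsFactors = FALSE)
}

run_marker_positions <- function(start_bp, end_bp, n) {
  if (n == 1) return(start_bp)
  start_bp + round((end_bp - start_bp) * (seq_len(n) - 1) / (n - 1))
}

#' Synthesise a panel realising one shared-homozygosity run
#'
#' Builds a six-affected panel with `n_snps` markers evenly spaced
#' between the exact boundary coordinates (all samples homozygous AA),
#' flanked by heterozygous markers so the run is maximal.
#'
#' @param n_snps number of markers in the run.
#' @param chrom chromosome label.
#' @param start_bp,end_bp exact boundary coordinates.
#' @param start_snp,end_snp ids for the boundary markers.
#' @param n_affected number of affected samples.
#' @return a `genotype_panel`.
#' @export
example_run_panel <- function(n_snps, chrom, start_bp, end_bp,
                              start_snp = "run_start", end_snp = "run_end",
                              n_affected = 6L) {
  bp <- run_marker_positions(start_bp, end_bp, n_snps)
  ids <- sprintf("%s_fx%d", chrom, seq_len(n_snps))
  ids[1] <- start_snp; ids[n_snps] <- end_snp
  flank_l <- start_bp - c(20000, 10000)
  flank_r <- end_bp + c(10000, 20000)
  all_bp <- c(flank_l, bp, flank_r)
  all_ids <- c(sprintf("%s_flkl%d", chrom, 1:2), ids,
               sprintf("%s_flkr%d", chrom, 1:2))
  markers <- data.frame(id = all_ids, chrom = chrom, pos_bp = all_bp,
                        cm = all_bp / 1e6, maf = NA_real_,
                        stringsAsFactors = FALSE)
  samples <- example_samples(n_affected)
  calls <- matrix("AA", nrow(markers), n_affected)
  calls[c(1, 2, nrow(markers) - 1, nrow(markers)), ] <- "AB"
  genotype_panel(markers, samples, calls)
}

#' Synthesise a panel of contiguous runs interrupted by single false
#' heterozygotes
#'
#' Takes several run rows on one chromosome (in genomic order) and
#' builds a panel in which each run is realised exactly, with one
#' single-sample heterozygous marker between consecutive runs — the
#' false-heterozygote interruption pattern that [bridge_runs()] repairs.
#' Where the printed boundary coordinate of one run equals the start of
#' the next (boundary markers shared between table rows), the later
#' run's start is nudged just past the interrupting marker; outer
#' boundaries are kept exact.
#'
#' @param runs data.frame rows with `snps`, `chrom`, `start_bp`,
#'   `end_bp`, `start_snp`, `end_snp` (one chromosome).
#' @param het_sample index of the affected sample carrying the false
#'   heterozygote calls.
#' @param n_affected number of affected samples.
#' @return a `genotype_panel`.
#' @export
example_contiguous_panel <- function(runs, het_sample = 1L, n_affected = 6L) {
  stopifnot(length(unique(runs$chrom)) == 1)
  runs <- runs[order(runs$start_bp), , drop = FALSE]
  chrom <- runs$chrom[1]
  starts <- runs$start_bp; ends <- runs$end_bp
  het_bp <- numeric(nrow(runs) - 1)
  for (i in seq_len(nrow(runs))[-1]) {
    if (starts[i] <= ends[i - 1]) {
      het_bp[i - 1] <- ends[i - 1] + 500
      starts[i] <- ends[i - 1] + 1000
    } else {
      het_bp[i - 1] <- floor((ends[i - 1] + starts[i]) / 2)
    }
  }
  bp <- c(); ids <- c(); type <- c()
  for (i in seq_len(nrow(runs))) {
    rbp <- run_marker_positions(starts[i], ends[i], runs$snps[i])
    rid <- sprintf("%s_r%d_%d", chrom, i, seq_len(runs$snps[i]))
    # boundary ids shared between table rows stay with their first
    # occurrence; the nudged later run keeps a generated id there
    if (!(runs$start_snp[i] %in% ids)) rid[1] <- runs$start_snp[i]
    if (!(runs$end_snp[i] %in% c(ids, rid[1]))) rid[length(rid)] <- runs$end_snp[i]
    bp <- c(bp, rbp); ids <- c(ids, rid); type <- c(type, rep("hom", runs$snps[i]))
    if (i < nrow(runs)) {
      bp <- c(bp, het_bp[i]); ids <- c(ids, sprintf("%s_het%d", chrom, i))
      type <- c(type, "het")
    }
  }
  flank_l <- min(bp) - c(20000, 10000)
  flank_r <- max(bp) + c(10000, 20000)
  bp <- c(flank_l, bp, flank_r)
  ids <- c(sprintf("%s_flkl%d", chrom, 1:2), ids, sprintf("%s_flkr%d", chrom, 1:2))
  type <- c("flank", "flank", type, "flank", "flank")
  markers <- data.frame(id = ids, chrom = chrom, pos_bp = bp,
                        cm = bp / 1e6, maf = NA_real_, stringsAsFactors = FALSE)
  samples <- example_samples(n_affected)
  calls <- matrix("AA", nrow(markers), n_affected)
  calls[type == "flank", ] <- "AB"
  calls[type == "het", het_sample] <- "AB"
  genotype_panel(markers, samples, calls)
}
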