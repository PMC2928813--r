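# Programmatic transcript fixtures. Everything here is synthetic
# sequence built in code; no reference gene models or genome builds are
# shipped or required.

#' Build a toy transcript model from explicit exon and intron sequences
#'
#' Sequences are given in transcript orientation; introns are expected to
#' end in AG (the constructor validates this). For minus-strand models
#' the genomic sequence is the reverse complement, with coordinates
#' flipped accordingly, which makes this a convenient generator for
#' strand-symmetry tests.
#'
#' @param exon_seqs character vector of exon sequences, 5'->3'.
#' @param intron_seqs character vector of intron sequences
#'   (length `length(exon_seqs) - 1`).
#' @param id,chrom identifiers.
#' @param strand `"+"` or `"-"`.
#' @param flank5,flank3 flanking genomic sequence outside the transcript.
#' @param seq_start genomic coordinate of the first base of the locus
#'   sequence.
#' @param validate passed to [transcript_model()].
#' @return a `transcript_model` whose CDS spans all exonic bases.
#' @export
make_toy_transcript <- function(exon_seqs, intron_seqs = character(),
                                id = "toy_tx", chrom = "toy", strand = "+",
                                flank5 = "CCCC", flank3 = "CCCC",
                                seq_start = 1001L, validate = TRUE) {
  n <- length(exon_seqs)
  stopifnot(n >= 1, length(intron_seqs) == n - 1)
  pieces <- character(0)
  starts <- integer(n); ends <- integer(n)
  pos <- nchar(flank5) + 1L
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + nchar(exon_seqs[i]) - 1L
    pieces <- c(pieces, exon_seqs[i])
    pos <- ends[i] + 1L
    if (i < n) {
      pieces <- c(pieces, intron_seqs[i])
      pos <- pos + nchar(intron_seqs[i])
    }
  }
  fwd <- paste0(flank5, paste(pieces, collapse = ""), flank3)
  L <- nchar(fwd)
  if (strand == "+") {
    seq <- fwd
    g_starts <- starts + seq_start - 1L
    g_ends <- ends + seq_start - 1L
  } else {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(fwd)))
    # transcript-forward local p maps to genomic seq_start + (L - p)
    g_starts <- seq_start + (L - ends)
    g_ends <- seq_start + (L - starts)
  }
  exons <- data.frame(start = g_starts, end = g_ends)
  cds_g <- c(min(exons$start), max(exons$end))
  transcript_model(id = id, chrom = chrom, strand = strand,
                   exons = exons,
                   cds_start = cds_g[1], cds_end = cds_g[2],
                   seq = seq, seq_start = seq_start, validate = validate)
}

#' Point substitution destroying a given acceptor AG
#'
#' Builds the G-to-A change at the last intronic base of the chosen
#' intron, in forward-genomic coordinates (complemented automatically for
#' minus-strand models).
#'
#' @param tx a `transcript_model`.
#' @param intron_index which intron's acceptor to destroy.
#' @return a [point_substitution()].
#' @export
acceptor_mutation <- function(tx, intron_index) {
  norm <- tx_forward(tx)
  if (intron_index < 1 || intron_index >= nrow(norm$exons)) {
    az_stop("no such intron", "autozyg_input_error")
  }
  p <- norm$exons$start[intron_index + 1] - 1L  # the G of the acceptor AG
  seq_end <- tx$seq_start + norm$len - 1L
  if (tx$strand == "+") {
    point_substitution(pos = p + tx$seq_start - 1L, ref = "G", alt = "A")
  } else {
    point_substitution(pos = seq_end - p + 1L, ref = "C", alt = "T")
  }
}

#' Synthetic 25-exon transcript emulating the LRSAM1 splice defect
#'
#' A fully synthetic stand-in (no real reference sequence) with the
#' architecture relevant to the acceptor mutation analysed by this
#' package: 25 coding exons, a 723-residue reference protein, and a
#' penultimate exon (24) that begins with an AG dinucleotide. Destroying
#' the acceptor of intron 23 makes the exon-internal AG the nearest
#' downstream acceptor, deleting two bases at the junction; the resulting
#' frameshift truncates the protein after residue 643.
#'
#' @return list with elements `tx` (the `transcript_model`) and
#'   `mutation` (the acceptor-destroying [point_substitution()]).
#' @export
synthetic_lrsam1_like <- function() {
  # coding prefix spread over exons 1-23: ATG + 642 x GCT = 1929 nt
  prefix <- paste0("ATG", strrep("GCT", 642))
  lens <- c(rep(84L, 22), 81L)
  stopifnot(sum(lens) == nchar(prefix))
  offs <- cumsum(c(0L, lens[-23]))
  exons_1_23 <- substring(prefix, offs + 1L, offs + lens)
  # exon 24 starts AG (cryptic acceptor, offset 2); after the 2-base
  # deletion the shifted frame opens on TAA, stopping after residue 643
  exon24 <- paste0("AGTAAA", strrep("GCT", 38))
  exon25 <- paste0(strrep("GCT", 40), "TAA")
  introns <- rep(paste0("GT", strrep("T", 26), "AG"), 24)
  tx <- make_toy_transcript(
    exon_seqs = c(exons_1_23, exon24, exon25),
    intron_seqs = introns,
    id = "synthetic_lrsam1_like", chrom = "chr9s", strand = "+",
    flank5 = strrep("C", 50), flank3 = strrep("C", 50),
    seq_start = 1001L)
  list(tx = tx, mutation = acceptor_mutation(tx, 23L))
}
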