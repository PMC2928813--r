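# Splice-acceptor disruption and its protein consequence.
#
# The model is deliberately minimal: the AG dinucleotide at the 3' end of
# an intron is the sole acceptor determinant, and when a point mutation
# destroys it the spliceosome is assumed to use the nearest downstream AG
# (the behaviour observed in patient RNA). Exonic bases skipped by the
# aberrant junction are deleted from the mature transcript; the mutant
# CDS is translated with the standard genetic code to the first in-frame
# stop. Branch points, polypyrimidine tracts, splice-strength scoring and
# donor sites are out of scope.

#' Construct a transcript model
#'
#' @param id transcript identifier.
#' @param chrom chromosome/locus label.
#' @param strand `"+"` or `"-"`. Minus-strand transcripts are internally
#'   reverse-complemented to a transcript-forward frame; all offsets are
#'   reported in transcript coordinates.
#' @param exons data.frame of genomic exon intervals (`start`, `end`,
#'   1-based inclusive, ascending, non-overlapping).
#' @param cds_start,cds_end genomic coordinates of the first/last CDS base
#'   (must fall in exons; `cds_start < cds_end` in genomic orientation).
#' @param seq genomic sequence covering the locus (character or
#'   `DNAString`), forward strand.
#' @param seq_start genomic coordinate of the first base of `seq`.
#' @param validate check that every intron ends in AG and the CDS length
#'   is a multiple of 3.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand, exons, cds_start, cds_end,
                             seq, seq_start = 1L, validate = TRUE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons <- exons[order(exons$start), , drop = FALSE]
  if (any(exons$start > exons$end)) az_stop("exon start > end", "autozyg_validation_error")
  if (nrow(exons) > 1 && any(exons$start[-1] <= exons$end[-nrow(exons)])) {
    az_stop("exons overlap", "autozyg_validation_error")
  }
  tx <- structure(list(id = id, chrom = chrom, strand = strand,
                       exons = exons, cds_start = cds_start,
                       cds_end = cds_end, seq = as.character(seq),
                       seq_start = as.integer(seq_start)),
                  class = "transcript_model")
  if (validate) {
    norm <- tx_forward(tx)
    n_ex <- nrow(norm$exons)
    if (n_ex > 1) {
      for (i in seq_len(n_ex - 1)) {
        acc <- substr(norm$seq, norm$exons$start[i + 1] - 2, norm$exons$start[i + 1] - 1)
        if (acc != "AG") {
          az_stop(sprintf("intron %d of %s does not end in AG (found '%s')", i, id, acc),
                  "autozyg_validation_error")
        }
      }
    }
    if (mature_cds_length(norm) %% 3 != 0) {
      az_stop(sprintf("CDS length of %s is not a multiple of 3", id),
              "autozyg_validation_error")
    }
  }
  tx
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s, strand %s): %d exons, CDS %d-%d\n",
              x$id, x$chrom, x$strand, nrow(x$exons), x$cds_start, x$cds_end))
  invisible(x)
}

# Normalize a transcript to a transcript-forward frame: for minus-strand
# models the sequence is reverse-complemented and coordinates flipped, so
# downstream logic is written once for the forward case.
tx_forward <- function(tx) {
  s <- tx$seq
  L <- nchar(s)
  seq_end <- tx$seq_start + L - 1L
  if (tx$strand == "+") {
    fwd <- s
    g2l <- function(p) p - tx$seq_start + 1L
  } else {
    fwd <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    g2l <- function(p) seq_end - p + 1L
  }
  a <- g2l(tx$exons$start); b <- g2l(tx$exons$end)
  exl <- data.frame(start = pmin(a, b), end = pmax(a, b))
  exl <- exl[order(exl$start), , drop = FALSE]
  rownames(exl) <- NULL
  cds <- range(c(g2l(tx$cds_start), g2l(tx$cds_end)))
  list(seq = fwd, exons = exl, cds_start = cds[1], cds_end = cds[2],
       g2l = g2l, strand = tx$strand, len = L)
}

# mature (spliced) coordinate of a transcript-forward exonic position
local_to_mature <- function(norm, p) {
  ex <- norm$exons
  lens <- ex$end - ex$start + 1L
  cum <- cumsum(c(0L, lens[-length(lens)]))
  i <- which(p >= ex$start & p <= ex$end)
  if (!length(i)) az_stop("position is not exonic", "autozyg_input_error")
  cum[i] + (p - ex$start[i] + 1L)
}

mature_seq <- function(norm) {
  paste(substring(norm$seq, norm$exons$start, norm$exons$end), collapse = "")
}

mature_cds_length <- function(norm) {
  local_to_mature(norm, norm$cds_end) - local_to_mature(norm, norm$cds_start) + 1L
}

#' Point substitution
#'
#' @param pos genomic position (forward-strand coordinate).
#' @param ref,alt reference and alternate base, forward strand.
#' @return a list of class `point_substitution`.
#' @export
point_substitution <- function(pos, ref, alt) {
  stopifnot(ref %in% c("A", "C", "G", "T"), alt %in% c("A", "C", "G", "T"), ref != alt)
  structure(list(pos = as.integer(pos), ref = ref, alt = alt),
            class = "point_substitution")
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Does a point substitution disrupt a splice acceptor?
#'
#' Returns the index of the intron whose terminal AG contains the mutated
#' base and whose post-mutation dinucleotide is no longer AG; `NA` when
#' every acceptor is left intact (exonic changes, donor-site changes, or
#' substitutions that keep an AG).
#'
#' @param tx a [transcript_model()].
#' @param mut a [point_substitution()] inside the transcript span. The
#'   reference base must match the model sequence.
#' @return integer intron index (5'->3' in transcript orientation) or `NA`.
#' @export
check_acceptor_disruption <- function(tx, mut) {
  norm <- tx_forward(tx)
  p <- norm$g2l(mut$pos)
  if (p < 1 || p > norm$len) {
    az_stop("mutation lies outside the transcript sequence", "autozyg_input_error")
  }
  ref_l <- if (tx$strand == "+") mut$ref else unname(COMPLEMENT[mut$ref])
  alt_l <- if (tx$strand == "+") mut$alt else unname(COMPLEMENT[mut$alt])
  have <- substr(norm$seq, p, p)
  if (have != ref_l) {
    az_stop(sprintf("reference base mismatch at %d: model has '%s', mutation says '%s' (transcript-forward '%s')",
                    mut$pos, have, mut$ref, ref_l), "autozyg_input_error")
  }
  n_ex <- nrow(norm$exons)
  if (n_ex < 2) return(NA_integer_)
  for (i in seq_len(n_ex - 1)) {
    a1 <- norm$exons$start[i + 1] - 2L
    a2 <- norm$exons$start[i + 1] - 1L
    if (p == a1 || p == a2) {
      di <- substring(norm$seq, a1, a2)
      substr(di, p - a1 + 1, p - a1 + 1) <- alt_l
      if (di != "AG") return(i)
    }
  }
  NA_integer_
}

#' Locate the cryptic acceptor used after acceptor disruption
#'
#' Scans the transcript sequence 3' of the disrupted acceptor for the
#' nearest AG dinucleotide within the downstream exon and returns the
#' number of exonic bases the aberrant junction removes relative to the
#' reference junction (an exon beginning `AG...` gives offset 2). When no
#' AG occurs within `window` bases the result carries status
#' `"NO_CRYPTIC"` rather than an error.
#'
#' @param tx a [transcript_model()].
#' @param intron_index index of the disrupted intron.
#' @param window maximum number of exonic bases scanned (default 200).
#' @return list with `status` (`"OK"`/`"NO_CRYPTIC"`) and `offset_nt`
#'   (`NA` when no cryptic acceptor is found).
#' @export
next_cryptic_acceptor <- function(tx, intron_index, window = 200L) {
  norm <- tx_forward(tx)
  if (intron_index < 1 || intron_index >= nrow(norm$exons)) {
    az_stop("no such intron", "autozyg_input_error")
  }
  es <- norm$exons$start[intron_index + 1]
  ee <- min(norm$exons$end[intron_index + 1], es + window - 1L)
  region <- substring(norm$seq, es, ee)
  hit <- regexpr("AG", region, fixed = TRUE)
  if (hit < 0) return(list(status = "NO_CRYPTIC", offset_nt = NA_integer_))
  list(status = "OK", offset_nt = as.integer(hit) + 1L)
}

translate_until_stop <- function(seq) {
  n <- nchar(seq) %/% 3
  if (n == 0) return(list(len_aa = 0L, stop_found = FALSE))
  codons <- substring(seq, 3 * (seq_len(n) - 1) + 1, 3 * seq_len(n))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  stop_i <- which(aa == "*")[1]
  if (is.na(stop_i)) list(len_aa = n, stop_found = FALSE)
  else list(len_aa = stop_i - 1L, stop_found = TRUE)
}

#' Consequence of splicing at an aberrant acceptor
#'
#' Deletes `offset_nt` bases of the downstream exon at the junction of
#' the given intron, rebuilds the mature CDS, translates from the
#' reference start codon to the first in-frame stop, and summarises the
#' effect: frameshift status, reference and mutant protein lengths, and
#' the number of codons left fully intact 5' of the junction. If no stop
#' is reached before the transcript end the consequence is flagged
#' `stop_lost`.
#'
#' @param tx a [transcript_model()].
#' @param intron_index index of the disrupted intron.
#' @param offset_nt exonic bases removed by the aberrant junction
#'   (0 reproduces the reference).
#' @return an object of class `splice_consequence`.
#' @export
apply_aberrant_splice <- function(tx, intron_index, offset_nt) {
  if (offset_nt < 0) az_stop("offset must be >= 0", "autozyg_input_error")
  norm <- tx_forward(tx)
  if (intron_index < 1 || intron_index >= nrow(norm$exons)) {
    az_stop("no such intron", "autozyg_input_error")
  }
  exon_len <- norm$exons$end[intron_index + 1] - norm$exons$start[intron_index + 1] + 1L
  if (offset_nt > exon_len) {
    az_stop(sprintf("offset %d exceeds downstream exon length %d", offset_nt, exon_len),
            "autozyg_input_error")
  }
  mat <- mature_seq(norm)
  mc_start <- local_to_mature(norm, norm$cds_start)
  mc_end <- local_to_mature(norm, norm$cds_end)
  junction <- local_to_mature(norm, norm$exons$end[intron_index])
  mut_mat <- if (offset_nt == 0) mat else
    paste0(substr(mat, 1, junction), substr(mat, junction + offset_nt + 1, nchar(mat)))
  new_start <- if (junction + 1 <= mc_start) mc_start - offset_nt else mc_start
  ref_len <- (mc_end - mc_start + 1L) %/% 3L - 1L
  tr <- translate_until_stop(substr(mut_mat, new_start, nchar(mut_mat)))
  cds_before <- max(0L, min(junction, mc_end) - mc_start + 1L)
  structure(list(
    transcript_id = tx$id,
    disrupted_intron_index = as.integer(intron_index),
    cryptic_offset_nt = as.integer(offset_nt),
    deleted_nt = as.integer(offset_nt),
    is_frameshift = offset_nt %% 3 != 0,
    ref_protein_len_aa = as.integer(ref_len),
    mut_protein_len_aa = as.integer(tr$len_aa),
    intact_prefix_aa = as.integer(cds_before %/% 3L),
    stop_lost = !tr$stop_found
  ), class = "splice_consequence")
}

#' @export
print.splice_consequence <- function(x, ...) {
  cat(sprintf("splice_consequence for %s\n", x$transcript_id))
  cat(sprintf("  disrupted intron: %d; exonic bases deleted at junction: %d\n",
              x$disrupted_intron_index, x$deleted_nt))
  cat(sprintf("  frameshift: %s%s\n", x$is_frameshift,
              if (x$stop_lost) " (no in-frame stop before transcript end)" else ""))
  cat(sprintf("  protein: %d aa (reference %d aa), intact prefix %d aa\n",
              x$mut_protein_len_aa, x$ref_protein_len_aa, x$intact_prefix_aa))
  invisible(x)
}

#' Full acceptor-mutation annotation pipeline
#'
#' Runs disruption detection, cryptic-acceptor search and consequence
#' computation in sequence.
#'
#' @param tx a [transcript_model()].
#' @param mut a [point_substitution()].
#' @param window search window for [next_cryptic_acceptor()].
#' @return a `splice_consequence`, or a list with a `status` field
#'   (`"NO_DISRUPTION"` / `"NO_CRYPTIC"`) when the pipeline stops early.
#' @export
annotate_splice_mutation <- function(tx, mut, window = 200L) {
  intron <- check_acceptor_disruption(tx, mut)
  if (is.na(intron)) return(list(status = "NO_DISRUPTION"))
  cr <- next_cryptic_acceptor(tx, intron, window)
  if (cr$status != "OK") {
    return(list(status = "NO_CRYPTIC", disrupted_intron_index = intron))
  }
  apply_aberrant_splice(tx, intron, cr$offset_nt)
}

#' Write a transcript model as GFF3 + FASTA
#'
#' The FASTA record is named `chrom:start-end` so the genomic offset of
#' the sequence survives the round trip.
#'
#' @param tx a [transcript_model()].
#' @param gff_path,fasta_path output paths.
#' @return invisibly, the two paths.
#' @export
write_transcript <- function(tx, gff_path, fasta_path) {
  seq_end <- tx$seq_start + nchar(tx$seq) - 1L
  mk <- function(type, start, end, attrs) {
    sprintf("%s\tautozyg\t%s\t%d\t%d\t.\t%s\t.\t%s",
            tx$chrom, type, start, end, tx$strand, attrs)
  }
  lines <- c("##gff-version 3",
             mk("mRNA", min(tx$exons$start), max(tx$exons$end),
                sprintf("ID=%s", tx$id)),
             mk("exon", tx$exons$start, tx$exons$end,
                sprintf("Parent=%s", tx$id)),
             mk("CDS", tx$cds_start, tx$cds_end,
                sprintf("Parent=%s", tx$id)))
  writeLines(lines, gff_path)
  dna <- Biostrings::DNAStringSet(tx$seq)
  names(dna) <- sprintf("%s:%d-%d", tx$chrom, tx$seq_start, seq_end)
  Biostrings::writeXStringSet(dna, fasta_path)
  invisible(c(gff = gff_path, fasta = fasta_path))
}

#' Read a transcript model from GFF3 + FASTA
#'
#' Expects one mRNA with exon and CDS children (the layout written by
#' [write_transcript()]).
#'
#' @param gff_path,fasta_path input paths.
#' @param validate passed to [transcript_model()].
#' @return a `transcript_model`.
#' @export
read_transcript <- function(gff_path, fasta_path, validate = TRUE) {
  gr <- rtracklayer::import(gff_path, format = "GFF3")
  types <- as.character(gr$type)
  ex <- gr[types == "exon"]
  cds <- gr[types == "CDS"]
  mrna <- gr[types == "mRNA"]
  if (!length(ex) || !length(cds) || !length(mrna)) {
    az_stop("GFF3 must contain mRNA, exon and CDS features", "autozyg_schema_error")
  }
  dna <- Biostrings::readDNAStringSet(fasta_path)
  header <- names(dna)[1]
  m <- regmatches(header, regexec("^(\\S+):(\\d+)-(\\d+)", header))[[1]]
  if (length(m) == 4) {
    chrom <- m[2]; seq_start <- as.integer(m[3])
  } else {
    chrom <- sub("\\s.*$", "", header); seq_start <- 1L
  }
  transcript_model(
    id = as.character(mrna$ID[1] %||% "tx1"),
    chrom = chrom,
    strand = as.character(GenomicRanges::strand(mrna))[1],
    exons = data.frame(start = GenomicRanges::start(ex), end = GenomicRanges::end(ex)),
    cds_start = min(GenomicRanges::start(cds)),
    cds_end = max(GenomicRanges::end(cds)),
    seq = as.character(dna[[1]]),
    seq_start = seq_start,
    validate = validate)
}
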