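# codon-aligned helper exons (alanine filler keeps frames stop-free)
ala <- function(n) strrep("GCT", n)
intr <- function(n = 30) paste0("GT", strrep("T", n - 4), "AG")

toy3 <- function(e3_first = "AGT", strand = "+") {
  # 3 exons, 21 codons incl. stop: reference protein 20 aa
  make_toy_transcript(
    exon_seqs = c(paste0("ATG", ala(6)), ala(7), paste0(e3_first, ala(5), "TAA")),
    intron_seqs = c(intr(), intr()), strand = strand)
}

test_that("acceptor disruption is detected only at intron-terminal AG", {
  tx <- toy3()
  mut <- acceptor_mutation(tx, 2)
  expect_equal(check_acceptor_disruption(tx, mut), 2L)

  # exonic substitution 10 bp into an exon: no acceptor involved
  ex2_start <- tx$exons$start[2]
  exonic <- point_substitution(ex2_start + 9, substr(tx$seq, ex2_start + 9 - tx$seq_start + 1,
                                                     ex2_start + 9 - tx$seq_start + 1), "A")
  expect_true(is.na(check_acceptor_disruption(tx, exonic)))

  # donor GT mutation: acceptors only
  don_pos <- tx$exons$end[1] + 1  # the G of the donor GT
  donor <- point_substitution(don_pos, "G", "A")
  expect_true(is.na(check_acceptor_disruption(tx, donor)))

  # reference mismatch is an input error
  bad <- point_substitution(mut$pos, "T", "A")
  expect_error(check_acceptor_disruption(tx, bad), "mismatch",
               class = "autozyg_input_error")
})

test_that("cryptic acceptor is the nearest downstream AG", {
  # exon beginning AG -> 2-base deletion
  tx2 <- toy3(e3_first = "AGT")
  expect_equal(next_cryptic_acceptor(tx2, 2)$offset_nt, 2L)
  # exon beginning GGAGT -> first AG ends 4 bases in
  tx4 <- make_toy_transcript(
    exon_seqs = c(paste0("ATG", ala(6)), ala(7), paste0("GGAGT", ala(4), "TTAA")),
    intron_seqs = c(intr(), intr()))
  expect_equal(next_cryptic_acceptor(tx4, 2)$offset_nt, 4L)
  # no AG at all within the window
  txno <- make_toy_transcript(
    exon_seqs = c(paste0("ATG", ala(6)), ala(7), paste0(strrep("TTT", 5), "TAA")),
    intron_seqs = c(intr(), intr()))
  res <- next_cryptic_acceptor(txno, 2)
  expect_equal(res$status, "NO_CRYPTIC")
  expect_true(is.na(res$offset_nt))
})

test_that("cryptic search agrees with a naive character scan", {
  set.seed(42)
  for (rep in 1:20) {
    e3 <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
    e3 <- paste0(e3, ala(2), "TAA")  # pad to length 39 (codon-aligned)
    tx <- make_toy_transcript(
      exon_seqs = c(paste0("ATG", ala(6)), ala(7), e3),
      intron_seqs = c(intr(), intr()))
    norm_start <- tx$exons$start[3] - tx$seq_start + 1
    expected <- oracle_first_ag(tx$seq, norm_start, norm_start + nchar(e3) - 1)
    got <- next_cryptic_acceptor(tx, 2)
    if (is.na(expected)) {
      expect_equal(got$status, "NO_CRYPTIC")
    } else {
      expect_equal(got$offset_nt, expected - norm_start + 1)
    }
  }
})

test_that("aberrant splice consequences match independent translation", {
  tx <- toy3(e3_first = "AGT")
  cons <- apply_aberrant_splice(tx, 2, 2)
  # independent oracle: rebuild the mutant CDS by string surgery and
  # translate it with Biostrings
  e1 <- paste0("ATG", ala(6)); e2 <- ala(7); e3 <- paste0("AGT", ala(5), "TAA")
  mut_cds <- paste0(e1, e2, substr(e3, 3, nchar(e3)))
  n_cod <- nchar(mut_cds) %/% 3
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(mut_cds, 1, 3 * n_cod))))
  stop_pos <- regexpr("*", aa, fixed = TRUE)
  exp_len <- if (stop_pos < 0) n_cod else stop_pos - 1
  expect_true(cons$is_frameshift)
  expect_equal(cons$ref_protein_len_aa, 20L)
  expect_equal(cons$stop_lost, stop_pos < 0)
  expect_equal(cons$mut_protein_len_aa, as.integer(exp_len))
  expect_equal(cons$intact_prefix_aa, (21 + 21) %/% 3)

  # in-frame deletion of one codon
  cons3 <- apply_aberrant_splice(tx, 2, 3)
  expect_false(cons3$is_frameshift)
  expect_equal(cons3$mut_protein_len_aa, 19L)

  # offset 0 reproduces the reference
  cons0 <- apply_aberrant_splice(tx, 2, 0)
  expect_false(cons0$is_frameshift)
  expect_equal(cons0$mut_protein_len_aa, cons0$ref_protein_len_aa)

  expect_error(apply_aberrant_splice(tx, 2, 1000), class = "autozyg_input_error")
})

test_that("frameshift flag tracks offset mod 3 over random offsets", {
  tx <- make_toy_transcript(
    exon_seqs = c(paste0("ATG", ala(6)), ala(7), paste0("AG", ala(20), "TTAA")),
    intron_seqs = c(intr(), intr()), validate = FALSE)
  set.seed(7)
  for (off in sample(0:12, 8)) {
    cons <- apply_aberrant_splice(tx, 2, off)
    expect_equal(cons$is_frameshift, off %% 3 != 0)
    expect_equal(cons$deleted_nt, off)
  }
})

test_that("minus-strand transcripts give identical consequences", {
  plus <- toy3(strand = "+")
  minus <- toy3(strand = "-")
  mut_p <- acceptor_mutation(plus, 2)
  mut_m <- acceptor_mutation(minus, 2)
  expect_equal(check_acceptor_disruption(minus, mut_m), 2L)
  cons_p <- annotate_splice_mutation(plus, mut_p)
  cons_m <- annotate_splice_mutation(minus, mut_m)
  for (f in c("deleted_nt", "is_frameshift", "ref_protein_len_aa",
              "mut_protein_len_aa", "intact_prefix_aa")) {
    expect_equal(cons_m[[f]], cons_p[[f]])
  }
})

test_that("GFF3 + FASTA round-trip preserves the model", {
  tx <- toy3()
  gff <- tempfile(fileext = ".gff3"); fa <- tempfile(fileext = ".fa")
  write_transcript(tx, gff, fa)
  back <- read_transcript(gff, fa)
  expect_equal(back$exons, tx$exons)
  expect_equal(back$strand, tx$strand)
  expect_equal(back$seq, tx$seq)
  expect_equal(back$seq_start, tx$seq_start)
  expect_equal(back$cds_start, tx$cds_start)
  cons <- annotate_splice_mutation(back, acceptor_mutation(back, 2))
  expect_equal(cons$deleted_nt, 2L)
})

test_that("the synthetic 25-exon model reproduces the full defect", {
  fx <- synthetic_lrsam1_like()
  expect_equal(nrow(fx$tx$exons), 25)
  cons <- annotate_splice_mutation(fx$tx, fx$mutation)
  expect_equal(cons$disrupted_intron_index, 23L)
  expect_equal(cons$deleted_nt, 2L)
  expect_true(cons$is_frameshift)
  expect_equal(cons$ref_protein_len_aa, 723L)
  expect_equal(cons$mut_protein_len_aa, 643L)
  expect_equal(cons$intact_prefix_aa, 643L)
  expect_false(cons$stop_lost)
})
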