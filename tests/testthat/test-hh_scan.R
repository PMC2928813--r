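test_that("homozygous subset keeps exactly the homozygous markers", {
  p <- make_test_panel(cbind(c("AA", "AB", "BB", NA, "AA")))
  h <- homozygous_subset(p, "s1")
  expect_equal(h$marker_idx, c(1L, 3L, 5L))
  expect_equal(h$allele, c("A", "B", "A"))

  p2 <- make_test_panel(cbind(rep("AB", 4)))
  expect_equal(nrow(homozygous_subset(p2, "s1")), 0)

  p3 <- make_test_panel(cbind(rep("AA", 4)))
  expect_equal(nrow(homozygous_subset(p3, "s1")), 4)

  expect_error(homozygous_subset(p, "nope"), class = "autozyg_lookup_error")
})

test_that("discordance points require opposite homozygotes", {
  p <- make_test_panel(matrix(c("AA", "AA", "AA",
                                "BB", "AB", "AA"), ncol = 2))
  haps <- lapply(p$samples$id, homozygous_subset, panel = p)
  # marker 1: A-hom vs B-hom -> discordant; marker 2: het is outside the
  # homozygosity haplotype; marker 3: concordant
  expect_equal(find_discordance_points(haps), 1L)
  expect_error(find_discordance_points(haps[1]), class = "autozyg_validation_error")
})

test_that("RCHH scan spans, splits at discordance, and respects the cM cutoff", {
  # 11 markers, 0..10 cM, all concordant -> one chromosome-wide region
  calls <- matrix("AA", 11, 2)
  cm <- 0:10
  p <- make_test_panel(calls, cm = cm)
  r <- shared_rcch(p, c("s1", "s2"), hh_config(cutoff_cm = 3))
  expect_equal(nrow(r), 1)
  expect_equal(r$start_idx, 1L)
  expect_equal(r$end_idx, 11L)
  expect_equal(r$genetic_length_cm, 10)

  # one B/B vs A/A discordance at the midpoint -> two ~5 cM regions,
  # neither containing the midpoint marker
  calls2 <- calls
  calls2[6, 1] <- "BB"
  p2 <- make_test_panel(calls2, cm = cm)
  r2 <- shared_rcch(p2, c("s1", "s2"), hh_config(cutoff_cm = 3))
  expect_equal(nrow(r2), 2)
  expect_equal(r2$start_idx, c(1L, 7L))
  expect_equal(r2$end_idx, c(5L, 11L))
  expect_true(all(r2$genetic_length_cm >= 3))

  # with cutoff above the fragment length nothing is reported
  r3 <- shared_rcch(p2, c("s1", "s2"), hh_config(cutoff_cm = 6))
  expect_equal(nrow(r3), 0)
})

test_that("regions split across large physical gaps between informative markers", {
  bp <- c(1e6, 1.1e6, 1.2e6, 1.7e6, 1.8e6)  # 500 kb gap between 3 and 4
  p <- make_test_panel(matrix("AA", 5, 2), bp = bp, cm = c(0, 2, 4, 6, 8))
  r <- shared_rcch(p, c("s1", "s2"), hh_config(cutoff_cm = 1, largegap_bp = 400000))
  expect_equal(nrow(r), 2)
  expect_equal(r$end_idx[1], 3L)
  expect_equal(r$start_idx[2], 4L)
  # a permissive gap keeps one region
  r2 <- shared_rcch(p, c("s1", "s2"), hh_config(cutoff_cm = 1, largegap_bp = 600000))
  expect_equal(nrow(r2), 1)
})

test_that("scan requires a repaired genetic map", {
  p <- make_test_panel(matrix("AA", 3, 2), cm = c(0.1, NA, 0.5))
  expect_error(shared_rcch(p, c("s1", "s2")), "interpolate_cm",
               class = "autozyg_precondition_error")
})

test_that("RCHH output is invariant under affected-sample permutation and
           raising the cutoff only shrinks the result", {
  for (sd in 1:5) {
    set.seed(sd)
    p <- random_panel(80, 5)
    ids <- p$samples$id
    cfg1 <- hh_config(cutoff_cm = 1)
    r_fwd <- shared_rcch(p, ids, cfg1)
    r_rev <- shared_rcch(p, rev(ids), cfg1)
    expect_equal(r_fwd$start_idx, r_rev$start_idx)
    expect_equal(r_fwd$end_idx, r_rev$end_idx)

    r_hi <- shared_rcch(p, ids, hh_config(cutoff_cm = 3))
    key <- function(r) paste(r$chrom, r$start_idx, r$end_idx)
    expect_true(all(key(r_hi) %in% key(r_fwd)))
  }
})

test_that("RCHH scan matches the brute-force enumeration and reported
           regions contain no discordance point", {
  for (sd in 1:10) {
    set.seed(100 + sd)
    p <- random_panel(60, 4)
    ids <- p$samples$id
    cfg <- hh_config(cutoff_cm = 0.5, largegap_bp = 300000)
    r <- shared_rcch(p, ids, cfg)
    expected <- oracle_rcch(p, ids, cfg$cutoff_cm, cfg$largegap_bp)
    got <- runs_as_pairs(data.frame(start_idx = r$start_idx, end_idx = r$end_idx))
    expect_equal(got, expected[order(vapply(expected, `[`, 0, 1))])
    # re-scan every region for discordance
    haps <- lapply(ids, homozygous_subset, panel = p)
    disc <- find_discordance_points(haps)
    for (i in seq_len(nrow(r))) {
      expect_length(intersect(disc, r$start_idx[i]:r$end_idx[i]), 0)
    }
  }
})

test_that("known-locus exclusion uses closed-interval overlap", {
  rcch <- data.frame(chrom = "1", start_bp = 10, end_bp = 20)
  loci <- data.frame(name = c("L1", "L2", "L3"), chrom = c("1", "1", "2"),
                     start_bp = c(15, 21, 10), end_bp = c(30, 30, 30))
  rep <- test_known_loci(rcch, loci)
  expect_equal(rep$verdict, c("OVERLAPPED", "EXCLUDED", "EXCLUDED"))
  expect_equal(rep$overlapping_region[1], "1:10-20")
  # empty region list excludes everything
  rep0 <- test_known_loci(rcch[0, ], loci)
  expect_true(all(rep0$verdict == "EXCLUDED"))
})

test_that("BED known-loci round-trip preserves 1-based closed coordinates", {
  loci <- data.frame(name = c("a", "b"), chrom = c("1", "X"),
                     start_bp = c(101, 5001), end_bp = c(200, 6000))
  f <- tempfile(fileext = ".bed")
  write_known_loci(loci, f)
  # BED on disk is 0-based half-open
  expect_equal(strsplit(readLines(f)[1], "\t")[[1]], c("1", "100", "200", "a"))
  back <- read_known_loci(f)
  expect_equal(back$start_bp, loci$start_bp)
  expect_equal(back$end_bp, loci$end_bp)
  expect_equal(back$name, loci$name)
})
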