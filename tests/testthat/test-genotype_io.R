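write_tmp <- function(lines) {
  f <- tempfile()
  writeLines(lines, f)
  f
}

test_that("AB coding is symmetric in allele order and handles missing calls", {
  mapf <- write_tmp(c("1\trs1\t0\t1000", "1\trs2\t0\t2000", "1\trs3\t0\t3000"))
  pedf <- write_tmp(c("F s1 0 0 1 2 A A A G 0 0",
                      "F s2 0 0 2 1 G A G G G G"))
  p <- read_panel(pedf, mapf)
  expect_equal(dim(p$calls), c(3L, 2L))
  # marker rs1: alleles {A,G}, A is lexicographically smaller -> allele A
  expect_equal(unname(p$calls["rs1", ]), c("AA", "AB"))
  # "A G" and "G A" both read as AB
  expect_equal(unname(p$calls["rs2", ]), c("AB", "BB"))
  # "0 0" is missing; a single-allele marker is homozygous A
  expect_equal(unname(p$calls["rs3", ]), c(NA_character_, "AA"))
  expect_equal(p$samples$status, c("affected", "unaffected"))
  expect_equal(p$samples$sex, c("male", "female"))
})

test_that("read/write round-trips calls, order and pedigree on random panels", {
  for (sd in 1:4) {
    set.seed(sd)
    p <- random_panel(30, 4, n_chrom = 3)
    # AB coding is defined only up to observed alleles: relabel markers
    # where allele A is never witnessed (only-BB markers read back as AA)
    for (i in seq_len(nrow(p$markers))) {
      g <- p$calls[i, ]
      if (!any(g %in% c("AA", "AB"))) p$calls[i, g == "BB" & !is.na(g)] <- "AA"
    }
    pedf <- tempfile(); mapf <- tempfile()
    write_panel(p, pedf, mapf)
    q <- read_panel(pedf, mapf)
    expect_identical(unname(q$calls), unname(p$calls))
    expect_identical(q$markers$id, p$markers$id)
    expect_identical(q$markers$pos_bp, p$markers$pos_bp)
    expect_identical(q$samples$status, p$samples$status)
  }
})

test_that("missing calls are emitted as 0 0 and writing an empty panel fails", {
  p <- make_test_panel(matrix(c("AA", NA, "AB", "BB"), 2))
  pedf <- tempfile(); mapf <- tempfile()
  write_panel(p, pedf, mapf)
  fields <- strsplit(readLines(pedf)[1], " ")[[1]]
  expect_equal(fields[7:10], c("A", "A", "0", "0"))
  p$samples <- p$samples[0, , drop = FALSE]
  p$calls <- p$calls[, 0, drop = FALSE]
  expect_error(write_panel(p, pedf, mapf), class = "autozyg_io_error")
})

test_that("parse and validation errors identify the offending row or marker", {
  mapf <- write_tmp(c("1\trs1\t0\t1000", "1\trs1\t0\t2000"))
  pedf <- write_tmp("F s1 0 0 1 2 A A A A")
  expect_error(read_panel(pedf, mapf), "duplicate marker",
               class = "autozyg_validation_error")

  mapf <- write_tmp(c("1\trs1\t0\t1000", "1\trs2\t0\t2000"))
  pedf_bad <- write_tmp(c("F s1 0 0 1 2 A A A A", "F s2 0 0 1 2 A A"))
  expect_error(read_panel(pedf_bad, mapf), "line 2",
               class = "autozyg_parse_error")

  pedf_tri <- write_tmp(c("F s1 0 0 1 2 A C A A", "F s2 0 0 1 2 G G A A"))
  expect_error(read_panel(pedf_tri, mapf), "more than two alleles",
               class = "autozyg_validation_error")
})

test_that("marker sort is natural by chromosome then position", {
  mapf <- write_tmp(c("10\trsA\t0\t500", "2\trsB\t0\t900", "X\trsC\t0\t100",
                      "2\trsD\t0\t100"))
  pedf <- write_tmp("F s1 0 0 0 0 A A A A A A A A")
  p <- read_panel(pedf, mapf)
  expect_equal(p$markers$id, c("rsD", "rsB", "rsA", "rsC"))
})

test_that("annotation reader fills fields, preserves invalid cM, enforces schema", {
  f <- write_tmp(c("snp\tchr\tbp\tcm\tmaf",
                   "rs1324475\t9\t122423730\t135.2\t0.21",
                   "rs_empty\t9\t122500000\t\t0.4",
                   "rs_zero\t9\t122600000\t0\t0.1"))
  ann <- read_annotation(f)
  expect_equal(ann$id, c("rs1324475", "rs_empty", "rs_zero"))
  expect_equal(ann$pos_bp[1], 122423730)
  expect_equal(ann$cm[1], 135.2)
  expect_true(is.na(ann$cm[2]))   # preserved for downstream repair
  expect_equal(ann$cm[3], 0)
  expect_equal(ann$maf[1], 0.21)

  f2 <- write_tmp(c("snp\tchr\tbp", "rs1\t1\t100"))
  expect_error(read_annotation(f2), "no column",
               class = "autozyg_schema_error")

  f3 <- write_tmp(c("snp\tchr\tbp\tcm\tmaf",
                    "rs1\t1\t100\t0.1\t0.2",
                    "rs2\t1\t100\t0.2\t0.2"))
  expect_error(read_annotation(f3), "rs1.*rs2|rs1, rs2",
               class = "autozyg_ordering_error")
})

test_that("pedigree validation rejects dangling parents and cycles", {
  m <- data.frame(id = "m1", chrom = "1", pos_bp = 100)
  s <- data.frame(id = c("a", "b"), father_id = c("zz", NA),
                  mother_id = NA_character_, sex = "unknown", status = "unknown")
  expect_error(genotype_panel(m, s, matrix("AA", 1, 2)),
               "not in the pedigree", class = "autozyg_validation_error")
  s2 <- data.frame(id = c("a", "b"), father_id = c("b", "a"),
                   mother_id = NA_character_, sex = "unknown", status = "unknown")
  expect_error(genotype_panel(m, s2, matrix("AA", 1, 2)),
               "cycle", class = "autozyg_validation_error")
})
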