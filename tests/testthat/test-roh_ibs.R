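test_that("shared IBS runs are found, sized inclusively, and sorted by SNP count", {
  # 40 conforming markers flanked by heterozygous ones
  calls <- rbind(matrix("AB", 2, 6), matrix("AA", 40, 6), matrix("AB", 2, 6))
  p <- make_test_panel(calls)
  r <- shared_ibs_runs(p, p$samples$id, scan_config(min_run_snps = 35))
  expect_equal(nrow(r), 1)
  expect_equal(r$n_snps, 40)
  expect_equal(r$start_idx, 3L)
  expect_equal(r$end_idx, 42L)
  expect_equal(r$size_bp, p$markers$pos_bp[42] - p$markers$pos_bp[3] + 1)
  expect_equal(run_size_bp(r), r$size_bp)

  # homozygous but not identical by state: no runs
  calls2 <- cbind(matrix("AA", 40, 5), rep("BB", 40))
  p2 <- make_test_panel(calls2)
  expect_equal(nrow(shared_ibs_runs(p2, p2$samples$id, scan_config(min_run_snps = 5))), 0)

  # a missing call breaks a run
  calls3 <- matrix("AA", 20, 3)
  calls3[10, 2] <- NA
  p3 <- make_test_panel(calls3)
  r3 <- shared_ibs_runs(p3, p3$samples$id, scan_config(min_run_snps = 5))
  expect_equal(runs_as_pairs(r3), list(c(1L, 9L), c(11L, 20L)))
  # descending SNP-count sort puts the 10-marker run first
  expect_equal(r3$n_snps, c(10L, 9L))
})

test_that("size convention is end - start + 1", {
  expect_equal(run_size_bp(data.frame(start_bp = 64801868, end_bp = 64929306)), 127439)
  expect_equal(run_size_bp(data.frame(start_bp = 29767744, end_bp = 29954834)), 187091)
  expect_equal(run_size_bp(data.frame(start_bp = 5, end_bp = 5)), 1)
})

test_that("scan matches the brute-force oracle and runs are maximal", {
  for (sd in 1:10) {
    set.seed(200 + sd)
    p <- random_panel(70, 4, probs = c(0.5, 0.12, 0.33, 0.05))
    ids <- p$samples$id
    r <- shared_ibs_runs(p, ids, scan_config(min_run_snps = 2))
    expect_equal(runs_as_pairs(r), oracle_ibs_runs(p, ids, 2))
    # maximality: one-marker extension violates the predicate
    conf <- !is.na(conforming <- {
      j <- match(ids, p$samples$id)
      apply(p$calls[, j, drop = FALSE], 1, function(g)
        if (!anyNA(g) && all(g %in% c("AA", "BB")) && length(unique(g)) == 1) g[1] else NA)
    })
    for (i in seq_len(nrow(r))) {
      s <- r$start_idx[i]; e <- r$end_idx[i]
      if (s > 1 && p$markers$chrom[s - 1] == r$chrom[i]) expect_false(conf[s - 1])
      if (e < nrow(p$markers) && p$markers$chrom[e + 1] == r$chrom[i]) expect_false(conf[e + 1])
    }
  }
})

test_that("bridging merges across single-sample false heterozygotes only", {
  # two 40-SNP runs separated by one single-sample het -> 81-SNP region
  calls <- rbind(matrix("AA", 40, 6),
                 c("AB", rep("AA", 5)),
                 matrix("AA", 40, 6))
  calls <- rbind(matrix("AB", 1, 6), calls, matrix("AB", 1, 6))
  p <- make_test_panel(calls)
  runs <- shared_ibs_runs(p, p$samples$id, scan_config())
  expect_equal(nrow(runs), 2)
  merged <- bridge_runs(runs, p)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_snps, 81)
  expect_equal(merged$n_runs, 2L)
  expect_equal(merged$n_bridged_snps, 1L)

  # an allele conflict at the gap marker never bridges
  calls2 <- calls
  calls2[42, ] <- c("AA", "BB", rep("AA", 4))
  p2 <- make_test_panel(calls2)
  runs2 <- shared_ibs_runs(p2, p2$samples$id, scan_config())
  expect_equal(nrow(bridge_runs(runs2, p2)), 2)

  # a missing call at the gap marker never bridges
  calls3 <- calls
  calls3[42, ] <- c(NA, rep("AA", 5))
  p3 <- make_test_panel(calls3)
  runs3 <- shared_ibs_runs(p3, p3$samples$id, scan_config())
  expect_equal(nrow(bridge_runs(runs3, p3)), 2)

  # two samples heterozygous exceeds the one-carrier default
  calls4 <- calls
  calls4[42, 1:2] <- "AB"
  p4 <- make_test_panel(calls4)
  runs4 <- shared_ibs_runs(p4, p4$samples$id, scan_config())
  expect_equal(nrow(bridge_runs(runs4, p4)), 2)
  expect_equal(nrow(bridge_runs(runs4, p4, config = scan_config(bridge_max_carriers = 2))), 1)
})

test_that("bridging is transitive and a zero gap budget is the identity", {
  blocks <- list(matrix("AA", 10, 6), matrix("AA", 12, 6), matrix("AA", 14, 6))
  calls <- matrix("AB", 0, 6)
  for (b in blocks) {
    calls <- rbind(calls, b, c("AB", rep("AA", 5)))
  }
  calls <- calls[-nrow(calls), , drop = FALSE]  # no trailing het
  p <- make_test_panel(calls)
  runs <- shared_ibs_runs(p, p$samples$id, scan_config(min_run_snps = 5))
  expect_equal(nrow(runs), 3)
  merged <- bridge_runs(runs, p)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$n_snps, 10 + 12 + 14 + 2)

  id0 <- bridge_runs(runs, p, config = scan_config(min_run_snps = 5, bridge_max_gap_snps = 0))
  expect_equal(nrow(id0), 3)
  expect_equal(sort(id0$start_idx), sort(runs$start_idx))
  expect_equal(sort(id0$end_idx), sort(runs$end_idx))
})

test_that("bridging refuses runs from a different panel", {
  p <- make_test_panel(matrix("AA", 10, 3))
  q <- make_test_panel(matrix("AA", 11, 3))
  runs <- shared_ibs_runs(p, p$samples$id, scan_config(min_run_snps = 5))
  expect_error(bridge_runs(runs, q), class = "autozyg_consistency_error")
})

test_that("unaffected contrast annotates and flags full matches", {
  calls <- cbind(matrix("AA", 30, 6),   # affecteds
                 rep("AA", 30),          # unaffected identical
                 c(rep("AB", 9), rep("AA", 21)))  # unaffected 30% het
  status <- c(rep("affected", 6), rep("unaffected", 2))
  p <- make_test_panel(calls, status = status)
  runs <- shared_ibs_runs(p, affected_ids(p), scan_config(min_run_snps = 10))
  merged <- bridge_runs(runs, p)
  ann <- contrast_unaffected(merged, p, unaffected_ids(p))
  expect_true(ann$not_segregating[1])
  expect_equal(ann$matching_unaffected[1], "s7")
  detail <- attr(ann, "contrast")
  expect_equal(detail$match_fraction[detail$sample == "s7"], 1.0)
  expect_equal(detail$match_fraction[detail$sample == "s8"], 0.7)
  expect_false(detail$matches[detail$sample == "s8"])

  # no unaffecteds: pass-through
  ann0 <- contrast_unaffected(merged, p, character(0))
  expect_false(any(ann0$not_segregating))
})

test_that("ranking orders by SNP count with the outlier ratio diagnostic", {
  regions <- data.frame(chrom = c("9", "18", "21"),
                        start_bp = c(1, 1, 1), end_bp = c(2, 2, 2),
                        n_snps = c(1359, 57, 49))
  rk <- rank_candidates(regions)
  expect_equal(rk$n_snps, c(1359, 57, 49))
  expect_equal(rk$ratio_to_next[1], 1359 / 57, tolerance = 1e-12)
  expect_equal(rk$ratio_to_next[3], Inf)

  single <- rank_candidates(regions[1, ])
  expect_equal(single$ratio_to_next, Inf)

  # tie at the top: stable order by (chrom, start)
  tie <- data.frame(chrom = c("2", "1"), start_bp = c(5, 9), end_bp = c(6, 10),
                    n_snps = c(50, 50))
  expect_equal(rank_candidates(tie)$chrom, c("1", "2"))
})
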