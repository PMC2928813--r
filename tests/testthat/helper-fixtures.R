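# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as naive per-marker loops, separate from the
# package's vectorised implementations.

make_test_panel <- function(calls, chrom = NULL, bp = NULL, cm = NULL,
                            status = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); k <- ncol(calls)
  if (is.null(chrom)) chrom <- rep("1", n)
  if (is.null(bp)) {
    bp <- integer(n)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      bp[i] <- 1e6 + 1e5 * (seq_along(i) - 1)
    }
  }
  if (is.null(cm)) cm <- bp / 1e6
  if (is.null(status)) status <- rep("affected", k)
  markers <- data.frame(id = sprintf("m%d", seq_len(n)), chrom = chrom,
                        pos_bp = bp, cm = cm, maf = NA_real_,
                        stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("s%d", seq_len(k)),
                        father_id = NA_character_, mother_id = NA_character_,
                        sex = "unknown", status = status,
                        stringsAsFactors = FALSE)
  genotype_panel(markers, samples, calls)
}

random_panel <- function(n_markers, n_samples, n_chrom = 2,
                         probs = c(0.42, 0.18, 0.35, 0.05)) {
  chrom <- as.character(sort(sample.int(n_chrom, n_markers, replace = TRUE)))
  bp <- integer(n_markers)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    bp[i] <- 1e6 + cumsum(sample(1e3:6e5, length(i), replace = TRUE))
  }
  calls <- matrix(sample(c("AA", "AB", "BB", NA), n_markers * n_samples,
                         replace = TRUE, prob = probs), n_markers)
  make_test_panel(calls, chrom = chrom, bp = bp)
}

# naive scan: test the shared-homozygous-IBS predicate marker by marker
oracle_ibs_runs <- function(panel, ids, min_run) {
  j <- match(ids, panel$samples$id)
  n <- nrow(panel$markers)
  conf <- logical(n)
  for (i in seq_len(n)) {
    g <- panel$calls[i, j]
    conf[i] <- !anyNA(g) && all(g %in% c("AA", "BB")) && length(unique(g)) == 1
  }
  res <- list()
  i <- 1L
  while (i <= n) {
    if (conf[i]) {
      start <- i
      while (i < n && conf[i + 1] &&
             panel$markers$chrom[i + 1] == panel$markers$chrom[i]) i <- i + 1L
      if (i - start + 1L >= min_run) res[[length(res) + 1]] <- c(start, i)
    }
    i <- i + 1L
  }
  res
}

# naive HH enumeration: walk each chromosome accumulating
# discordance-free, gap-free stretches
oracle_rcch <- function(panel, ids, cutoff, largegap) {
  m <- panel$markers
  j <- match(ids, panel$samples$id)
  n <- nrow(m)
  discord <- informative <- logical(n)
  for (i in seq_len(n)) {
    g <- panel$calls[i, j]
    has_a <- any(g == "AA", na.rm = TRUE)
    has_b <- any(g == "BB", na.rm = TRUE)
    discord[i] <- has_a && has_b
    informative[i] <- has_a || has_b
  }
  segs <- list()
  for (ch in unique(m$chrom)) {
    idx <- which(m$chrom == ch)
    brk <- logical(length(idx))
    infl <- which(informative[idx])
    if (length(infl) > 1) {
      for (t in seq_len(length(infl) - 1)) {
        if (m$pos_bp[idx[infl[t + 1]]] - m$pos_bp[idx[infl[t]]] > largegap) {
          brk[infl[t]] <- TRUE
        }
      }
    }
    start <- NULL
    for (i in seq_along(idx)) {
      gi <- idx[i]
      if (discord[gi]) {
        if (!is.null(start)) segs[[length(segs) + 1]] <- c(start, idx[i - 1])
        start <- NULL
        next
      }
      if (is.null(start)) start <- gi
      if (brk[i]) {
        segs[[length(segs) + 1]] <- c(start, gi)
        start <- NULL
      }
    }
    if (!is.null(start)) segs[[length(segs) + 1]] <- c(start, idx[length(idx)])
  }
  Filter(function(s) m$cm[s[2]] - m$cm[s[1]] >= cutoff, segs)
}

# character-by-character scan for the first AG at or after `from`
oracle_first_ag <- function(seq_str, from, to) {
  chars <- strsplit(seq_str, "")[[1]]
  for (i in seq(from, min(to, length(chars)) - 1)) {
    if (chars[i] == "A" && chars[i + 1] == "G") return(i + 1)
  }
  NA_integer_
}

runs_as_pairs <- function(runs) {
  if (nrow(runs) == 0) return(list())
  o <- order(runs$start_idx)
  lapply(o, function(i) c(runs$start_idx[i], runs$end_idx[i]))
}

top_candidate_hits_truth <- function(sim) {
  rk <- rank_candidates(bridge_runs(
    shared_ibs_runs(sim$panel, affected_ids(sim$panel)), sim$panel))
  nrow(rk) > 0 && rk$chrom[1] == sim$truth$causal_chrom &&
    rk$start_bp[1] <= sim$truth$causal_bp &&
    rk$end_bp[1] >= sim$truth$causal_bp
}
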