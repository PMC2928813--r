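# Gene-dropping simulator for consanguineous pedigrees.
#
# Founder haplotypes are drawn independently per marker from per-marker
# B-allele frequencies (no linkage disequilibrium among founders: runs of
# shared homozygosity in descendants then arise from identity by descent,
# which is the structure the scans must detect). Transmission follows the
# Haldane no-interference model: crossover between adjacent markers with
# probability (1 - exp(-2d))/2 for map distance d Morgans. Autozygosity
# of the designated affecteds at the causal locus is enforced by staged
# rejection: each meiosis on the (unique, precomputed) descent paths from
# the causal founder is redrawn until it transmits the carrier haplotype
# intact across the target window, which keeps conditioning exact while
# avoiding the astronomically small acceptance rate of whole-pedigree
# rejection for six jointly autozygous individuals.

#' A multiply consanguineous example pedigree
#'
#' 23 members over four generations: three siblings (children of the top
#' founder couple) marry in, and their children form three first-cousin
#' matings, each producing two affected and one unaffected child — six
#' affecteds in three sibships, with multiple consanguineous loops
#' through the founder couple.
#'
#' @return a sample data.frame (`id`, `father_id`, `mother_id`, `sex`,
#'   `status`) suitable for [simulate_panel()].
#' @export
example_pedigree <- function() {
  p <- function(id, f, m, sex, status = "unknown") {
    data.frame(id = id, father_id = f, mother_id = m, sex = sex,
               status = status, stringsAsFactors = FALSE)
  }
  rbind(
    p("F1", NA, NA, "male"), p("F2", NA, NA, "female"),
    p("S1", NA, NA, "female"), p("S2", NA, NA, "male"), p("S3", NA, NA, "female"),
    p("B1", "F1", "F2", "male"), p("B2", "F1", "F2", "female"),
    p("B3", "F1", "F2", "male"),
    p("C1", "B1", "S1", "male"), p("C2", "B1", "S1", "male"),
    p("C3", "S2", "B2", "female"), p("C4", "S2", "B2", "male"),
    p("C5", "B3", "S3", "female"), p("C6", "B3", "S3", "female"),
    p("A1", "C1", "C3", "male", "affected"),
    p("A2", "C1", "C3", "female", "affected"),
    p("U1", "C1", "C3", "male", "unaffected"),
    p("A3", "C4", "C5", "male", "affected"),
    p("A4", "C4", "C5", "female", "affected"),
    p("U2", "C4", "C5", "female", "unaffected"),
    p("A5", "C2", "C6", "male", "affected"),
    p("A6", "C2", "C6", "female", "affected"),
    p("U3", "C2", "C6", "male", "unaffected"))
}

#' Default synthetic marker map
#'
#' Evenly spaced markers at a uniform 1 cM/Mb recombination rate — a
#' deliberately featureless map adequate for run-detection testing (real
#' array maps are denser and locally uneven). The defaults give
#' chromosomes of realistic genetic length (~150 cM) at a desk-scale
#' marker count, so autozygous tracts localise within a chromosome
#' instead of spanning it.
#'
#' @param n_chrom number of chromosomes.
#' @param n_per_chrom markers per chromosome.
#' @param spacing_bp physical spacing between markers.
#' @param cm_per_mb uniform recombination rate.
#' @param start_bp position of the first marker on each chromosome.
#' @return a marker data.frame (`id`, `chrom`, `pos_bp`, `cm`).
#' @export
default_marker_map <- function(n_chrom = 2L, n_per_chrom = 1500L,
                               spacing_bp = 100000L, cm_per_mb = 1.0,
                               start_bp = 1e6) {
  out <- lapply(seq_len(n_chrom), function(ch) {
    bp <- start_bp + spacing_bp * (seq_len(n_per_chrom) - 1)
    data.frame(id = sprintf("snp%d_%d", ch, seq_len(n_per_chrom)),
               chrom = as.character(ch), pos_bp = bp,
               cm = bp / 1e6 * cm_per_mb, maf = NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulation configuration
#'
#' @param markers marker map data.frame (see [default_marker_map()]).
#' @param founder_freqs per-marker B-allele frequency among founders;
#'   `NULL` draws them uniformly from `[0.05, 0.5]` at simulation time.
#' @param causal_chrom,causal_bp implant location; defaults to the middle
#'   marker of the first chromosome.
#' @param causal_founder id of the founder whose first haplotype carries
#'   the causal allele.
#' @param target_region_snps intended minimum autozygous tract width in
#'   markers: conditioned meioses transmit the carrier haplotype intact
#'   across a window of this many markers around the causal position.
#' @param het_error_rate probability that a truly homozygous call is
#'   emitted as heterozygous (the one-directional false-heterozygote
#'   error model).
#' @param missing_rate probability that any call is emitted as missing
#'   (default 0: the interruption model motivating this simulator is
#'   false heterozygote calls on near-complete array data; missingness
#'   can be switched on to study its fragmenting effect, since missing
#'   calls break runs and are never bridged).
#' @param seed RNG seed; all randomness in [simulate_panel()] flows from it.
#' @param max_attempts per-meiosis rejection budget for the autozygosity
#'   conditioning.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(markers = default_marker_map(),
                       founder_freqs = NULL,
                       causal_chrom = NULL, causal_bp = NULL,
                       causal_founder = "F1",
                       target_region_snps = 300L,
                       het_error_rate = 5e-4, missing_rate = 0,
                       seed = 1L, max_attempts = 1000L) {
  stopifnot(het_error_rate >= 0, het_error_rate <= 1,
            missing_rate >= 0, missing_rate <= 1, target_region_snps >= 1)
  if (is.null(causal_chrom)) causal_chrom <- markers$chrom[1]
  on_ch <- which(markers$chrom == causal_chrom)
  if (!length(on_ch)) az_stop("causal chromosome has no markers", "autozyg_validation_error")
  if (is.null(causal_bp)) causal_bp <- markers$pos_bp[on_ch[ceiling(length(on_ch) / 2)]]
  structure(list(markers = markers, founder_freqs = founder_freqs,
                 causal_chrom = causal_chrom, causal_bp = causal_bp,
                 causal_founder = causal_founder,
                 target_region_snps = as.integer(target_region_snps),
                 het_error_rate = het_error_rate, missing_rate = missing_rate,
                 seed = as.integer(seed), max_attempts = as.integer(max_attempts)),
            class = "sim_config")
}

topo_order <- function(pedigree) {
  ids <- pedigree$id
  placed <- character(0)
  ord <- character(0)
  while (length(placed) < length(ids)) {
    ready <- ids[!(ids %in% placed) &
                 (is.na(pedigree$father_id) | pedigree$father_id %in% placed) &
                 (is.na(pedigree$mother_id) | pedigree$mother_id %in% placed)]
    if (!length(ready)) az_stop("pedigree is cyclic or has missing parents",
                                "autozyg_validation_error")
    ord <- c(ord, ready)
    placed <- c(placed, ready)
  }
  ord
}

founder_ids <- function(pedigree) {
  pedigree$id[is.na(pedigree$father_id) & is.na(pedigree$mother_id)]
}

#' Simulate founder haplotypes
#'
#' Two haplotypes per founder; the B allele is drawn independently per
#' marker with the per-marker founder frequency. Haplotypes carry unique
#' integer origin labels so descent can be traced exactly.
#'
#' @param pedigree sample data.frame.
#' @param config a [sim_config()]. Uses the current RNG state.
#' @return named list (per founder) of two haplotypes, each a list with
#'   `al` (0 = A, 1 = B) and `or` (origin label); attribute
#'   `"causal_origin"` records the label of the designated carrier
#'   haplotype (first haplotype of `config$causal_founder`).
#' @export
simulate_founders <- function(pedigree, config) {
  fids <- founder_ids(pedigree)
  n <- nrow(config$markers)
  freqs <- config$founder_freqs %||% stats::runif(n, 0.05, 0.5)
  if (length(freqs) == 1) freqs <- rep(freqs, n)
  stopifnot(length(freqs) == n, all(freqs >= 0 & freqs <= 1))
  pool <- list()
  lab <- 0L
  for (f in fids) {
    h <- lapply(1:2, function(k) {
      lab <<- lab + 1L
      list(al = stats::rbinom(n, 1L, freqs), or = rep(lab, n))
    })
    pool[[f]] <- h
  }
  if (!is.null(config$causal_founder)) {
    if (!(config$causal_founder %in% fids)) {
      az_stop(sprintf("causal founder '%s' is not a founder of this pedigree",
                      config$causal_founder), "autozyg_validation_error")
    }
    attr(pool, "causal_origin") <- pool[[config$causal_founder]][[1]]$or[1]
  }
  attr(pool, "freqs") <- freqs
  pool
}

#' One meiosis indicator under the Haldane model
#'
#' Draws, per chromosome, a starting parental haplotype and crossover
#' events between adjacent markers with probability `(1 - exp(-2d))/2`
#' for map distance `d` Morgans; `d = 0` co-transmits adjacent alleles.
#'
#' @param markers marker data.frame with `chrom` and `cm`.
#' @return list with `choice` (1/2 per marker) and `n_crossovers`.
#' @export
meiosis_indicator <- function(markers) {
  n <- nrow(markers)
  ind <- integer(n)
  nco <- 0L
  for (ch in unique(markers$chrom)) {
    idx <- which(markers$chrom == ch)
    start <- sample.int(2L, 1L)
    if (length(idx) > 1) {
      d <- diff(markers$cm[idx]) / 100
      p <- 0.5 * (1 - exp(-2 * d))
      sw <- stats::rbinom(length(d), 1L, p)
      ind[idx] <- 1L + (start - 1L + cumsum(c(0L, sw))) %% 2L
      nco <- nco + sum(sw)
    } else {
      ind[idx] <- start
    }
  }
  list(choice = ind, n_crossovers = nco)
}

# The meioses that must transmit the causal haplotype: for every affected,
# both parental transmissions; recursively, for every required carrier,
# the transmission from one parent with a descent path to the causal
# founder (father preferred when both qualify).
required_transmissions <- function(pedigree, affecteds, founder) {
  ids <- pedigree$id
  fa <- function(x) pedigree$father_id[match(x, ids)]
  mo <- function(x) pedigree$mother_id[match(x, ids)]
  reach <- founder
  repeat {
    add <- ids[!(ids %in% reach) & ((fa(ids) %in% reach) | (mo(ids) %in% reach))]
    if (!length(add)) break
    reach <- c(reach, add)
  }
  req <- list()
  need <- character(0)
  for (a in affecteds) {
    f <- fa(a); m <- mo(a)
    if (is.na(f) || is.na(m) || !(f %in% reach) || !(m %in% reach)) {
      az_stop(sprintf("pedigree does not admit autozygosity at the causal locus: affected '%s' lacks a biparental descent path from founder '%s'",
                      a, founder), "autozyg_simulation_error")
    }
    req[[length(req) + 1]] <- c(a, f)
    req[[length(req) + 1]] <- c(a, m)
    need <- union(need, c(f, m))
  }
  done <- character(0)
  while (length(need)) {
    x <- need[1]; need <- need[-1]
    if (x %in% done) next
    done <- c(done, x)
    if (x == founder) next
    f <- fa(x); m <- mo(x)
    if (is.na(f) && is.na(m)) {
      az_stop(sprintf("founder '%s' cannot inherit the causal haplotype from '%s'", x, founder),
              "autozyg_simulation_error")
    }
    parent <- if (!is.na(f) && f %in% reach) f else if (!is.na(m) && m %in% reach) m else
      az_stop(sprintf("no descent path from '%s' to required carrier '%s'", founder, x),
              "autozyg_simulation_error")
    req[[length(req) + 1]] <- c(x, parent)
    need <- union(need, parent)
  }
  unique(vapply(req, paste, character(1), collapse = "->"))
}

do_meiosis <- function(parent_haps, markers, cond, required, max_attempts) {
  attempts <- if (required) max_attempts else 1L
  ci <- NA_integer_
  if (required) {
    carries <- vapply(parent_haps, function(h) h$or[cond$causal_idx] == cond$causal_origin, TRUE)
    if (!any(carries)) {
      az_stop("internal: required transmission from a non-carrier parent",
              "autozyg_simulation_error")
    }
    ci <- which(carries)[1]
  }
  for (att in seq_len(attempts)) {
    res <- meiosis_indicator(markers)
    ind <- res$choice
    if (!required || all(ind[cond$win] == ci)) {
      al <- ifelse(ind == 1L, parent_haps[[1]]$al, parent_haps[[2]]$al)
      or <- ifelse(ind == 1L, parent_haps[[1]]$or, parent_haps[[2]]$or)
      return(list(al = al, or = or, n_crossovers = res$n_crossovers))
    }
  }
  az_stop(sprintf("autozygosity conditioning failed after %d attempts; pedigree and causal locus may be incompatible", max_attempts),
          "autozyg_simulation_error")
}

#' Drop genes through a pedigree
#'
#' Transmits recombinant founder haplotypes down the pedigree in
#' topological order. When `cond` is supplied (see
#' [condition_on_autozygosity()]), the meioses on the descent paths from
#' the causal founder are redrawn until they transmit the carrier
#' haplotype intact across the target window.
#'
#' @param pedigree sample data.frame.
#' @param pool founder haplotypes from [simulate_founders()].
#' @param markers marker map.
#' @param cond `NULL` for an unconditioned drop, or the conditioning
#'   descriptor built by [condition_on_autozygosity()].
#' @param max_attempts per-meiosis rejection budget.
#' @return named list per individual of two haplotypes (`al`, `or`).
#' @export
drop_genes <- function(pedigree, pool, markers, cond = NULL,
                       max_attempts = 1000L) {
  ord <- topo_order(pedigree)
  ids <- pedigree$id
  req <- if (is.null(cond)) character(0) else cond$required
  haps <- list()
  for (x in ord) {
    i <- match(x, ids)
    f <- pedigree$father_id[i]; m <- pedigree$mother_id[i]
    if (is.na(f) && is.na(m)) {
      if (is.null(pool[[x]])) az_stop(sprintf("founder '%s' has no haplotypes", x),
                                      "autozyg_consistency_error")
      haps[[x]] <- pool[[x]]
    } else if (!is.na(f) && !is.na(m)) {
      hp <- do_meiosis(haps[[f]], markers, cond,
                       paste(x, f, sep = "->") %in% req, max_attempts)
      hm <- do_meiosis(haps[[m]], markers, cond,
                       paste(x, m, sep = "->") %in% req, max_attempts)
      haps[[x]] <- list(hp[c("al", "or")], hm[c("al", "or")])
    } else {
      az_stop(sprintf("sample '%s' has exactly one recorded parent", x),
              "autozyg_validation_error")
    }
  }
  haps
}

#' Build the autozygosity conditioning descriptor
#'
#' Identifies the causal marker, the no-recombination window of
#' `target_region_snps` markers around it, and the set of meioses that
#' must transmit the causal founder haplotype so that every designated
#' affected is homozygous by descent at the causal position.
#'
#' @param pedigree sample data.frame with affected statuses.
#' @param config a [sim_config()].
#' @param causal_origin origin label of the carrier haplotype (attribute
#'   of [simulate_founders()] output).
#' @return conditioning descriptor for [drop_genes()].
#' @export
condition_on_autozygosity <- function(pedigree, config, causal_origin) {
  m <- config$markers
  on_ch <- which(m$chrom == config$causal_chrom)
  causal_idx <- on_ch[which.min(abs(m$pos_bp[on_ch] - config$causal_bp))]
  half <- config$target_region_snps %/% 2L
  lo <- max(min(on_ch), causal_idx - half)
  hi <- min(max(on_ch), causal_idx + half)
  affecteds <- pedigree$id[pedigree$status == "affected"]
  list(causal_idx = causal_idx, causal_origin = causal_origin,
       win = lo:hi,
       required = required_transmissions(pedigree, affecteds,
                                         config$causal_founder))
}

haps_to_calls <- function(haps, sample_ids, n_markers) {
  calls <- matrix(NA_character_, n_markers, length(sample_ids))
  for (j in seq_along(sample_ids)) {
    h <- haps[[sample_ids[j]]]
    nb <- h[[1]]$al + h[[2]]$al
    calls[, j] <- GENOTYPE_LEVELS[nb + 1L]
  }
  calls
}

#' Apply the one-directional genotyping-error model
#'
#' Independently per cell, a truly homozygous call becomes heterozygous
#' with probability `het_error_rate`, and any call becomes missing with
#' probability `missing_rate`. Heterozygous truth calls are never
#' converted to homozygous: interruptions of autozygous runs are modelled
#' as false heterozygote calls only.
#'
#' @param panel a `genotype_panel`.
#' @param config a [sim_config()] (only the two rates are used). Uses the
#'   current RNG state.
#' @return list with the perturbed `panel` and a `log` data.frame of
#'   perturbed cells (`marker_id`, `sample_id`, `truth`, `observed`).
#' @export
add_genotyping_error <- function(panel, config) {
  calls <- panel$calls
  hom <- !is.na(calls) & calls != "AB"
  flip <- hom & matrix(stats::runif(length(calls)) < config$het_error_rate,
                       nrow(calls))
  miss <- !is.na(calls) & matrix(stats::runif(length(calls)) < config$missing_rate,
                                 nrow(calls))
  new_calls <- calls
  new_calls[flip] <- "AB"
  new_calls[miss] <- NA_character_
  touched <- which(flip | miss, arr.ind = TRUE)
  log <- data.frame(
    marker_id = panel$markers$id[touched[, 1]],
    sample_id = panel$samples$id[touched[, 2]],
    truth = calls[touched],
    observed = new_calls[touched],
    stringsAsFactors = FALSE)
  out <- panel
  out$calls <- new_calls
  list(panel = out, log = log)
}

ibd_tract <- function(h, on_ch, causal_idx, causal_origin) {
  ok <- h[[1]]$or[on_ch] == causal_origin & h[[2]]$or[on_ch] == causal_origin
  ci <- match(causal_idx, on_ch)
  if (!ok[ci]) return(NULL)
  lo <- ci; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- ci; while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  c(on_ch[lo], on_ch[hi])
}

#' Simulate a pedigree genotype panel with an implanted autozygous tract
#'
#' End-to-end generator: founder haplotypes, conditioned gene drop,
#' genotype calls, and the genotyping-error model, with full ground
#' truth. All randomness flows from `config$seed`.
#'
#' The recorded truth contains, per affected, the autozygous
#' (homozygous-by-descent) tract around the causal position; their
#' intersection; and the *detectable* tract — the intersection extended
#' while every affected remains homozygous for the identical allele in
#' the error-free calls. The detectable tract is what any
#' identical-by-state scan can recover at best: chance identity in state
#' immediately beyond an identity-by-descent boundary is common, so the
#' IBS-visible tract is generally a superset of the IBD intersection.
#'
#' @param pedigree sample data.frame (default [example_pedigree()]).
#' @param config a [sim_config()].
#' @return an object of class `sim_result`: list with `panel` (perturbed
#'   calls), `truth` (causal marker/position, per-affected IBD tracts,
#'   their intersection, the detectable tract, founder freqs, the
#'   perturbation log) and `config`.
#' @export
simulate_panel <- function(pedigree = example_pedigree(),
                           config = sim_config()) {
  set.seed(config$seed)
  markers <- config$markers
  pool <- simulate_founders(pedigree, config)
  causal_origin <- attr(pool, "causal_origin")
  cond <- condition_on_autozygosity(pedigree, config, causal_origin)
  haps <- drop_genes(pedigree, pool, markers, cond, config$max_attempts)

  calls <- haps_to_calls(haps, pedigree$id, nrow(markers))
  markers$maf <- pmin(attr(pool, "freqs"), 1 - attr(pool, "freqs"))
  clean <- genotype_panel(markers, pedigree, calls)

  affecteds <- pedigree$id[pedigree$status == "affected"]
  on_ch <- which(markers$chrom == config$causal_chrom)
  tracts <- lapply(affecteds, function(a)
    ibd_tract(haps[[a]], on_ch, cond$causal_idx, causal_origin))
  names(tracts) <- affecteds
  if (any(vapply(tracts, is.null, TRUE))) {
    az_stop("internal: an affected is not autozygous after conditioning",
            "autozyg_simulation_error")
  }
  inter <- c(max(vapply(tracts, `[`, 0, 1)), min(vapply(tracts, `[`, 0, 2)))

  # detectable tract: extend the IBD intersection while all affecteds
  # stay homozygous for the identical allele in the error-free calls
  ja <- match(affecteds, pedigree$id)
  conf_at <- function(i) {
    g <- calls[i, ja]
    !anyNA(g) && all(g != "AB") && length(unique(g)) == 1
  }
  lo <- inter[1]; hi <- inter[2]
  while (lo > min(on_ch) && conf_at(lo - 1L)) lo <- lo - 1L
  while (hi < max(on_ch) && conf_at(hi + 1L)) hi <- hi + 1L

  err <- add_genotyping_error(clean, config)
  structure(list(
    panel = err$panel,
    truth = list(
      causal_idx = cond$causal_idx,
      causal_chrom = config$causal_chrom,
      causal_bp = markers$pos_bp[cond$causal_idx],
      causal_founder = config$causal_founder,
      causal_origin = causal_origin,
      affecteds = affecteds,
      ibd_tracts = tracts,
      ibd_intersection_idx = inter,
      detectable_idx = c(lo, hi),
      detectable_bp = c(markers$pos_bp[lo], markers$pos_bp[hi]),
      founder_freqs = attr(pool, "freqs"),
      perturbation_log = err$log),
    config = config), class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  t <- x$truth
  cat(sprintf("sim_result: %d markers x %d samples, causal %s:%d\n",
              nrow(x$panel$markers), nrow(x$panel$samples),
              t$causal_chrom, as.integer(t$causal_bp)))
  cat(sprintf("  detectable tract: markers %d-%d (%d SNPs); %d perturbed cells\n",
              t$detectable_idx[1], t$detectable_idx[2],
              t$detectable_idx[2] - t$detectable_idx[1] + 1L,
              nrow(t$perturbation_log)))
  invisible(x)
}

#' Check Mendelian consistency of a genotype panel
#'
#' Independent validator: for every child with both parents in the panel
#' and every marker, tests whether the trio of AB-coded genotypes is
#' compatible with Mendelian transmission (missing calls are treated as
#' compatible).
#'
#' @param panel a `genotype_panel`.
#' @return data.frame of violations (zero rows when consistent).
#' @export
check_mendelian <- function(panel) {
  s <- panel$samples
  g <- panel$calls
  has_a <- function(x) is.na(x) | x != "BB"
  has_b <- function(x) is.na(x) | x != "AA"
  out <- list()
  for (i in which(!is.na(s$father_id) & !is.na(s$mother_id))) {
    child <- g[, match(s$id[i], s$id)]
    f <- g[, match(s$father_id[i], s$id)]
    m <- g[, match(s$mother_id[i], s$id)]
    ok <- rep(TRUE, length(child))
    ok[which(child == "AA")] <- (has_a(f) & has_a(m))[which(child == "AA")]
    ok[which(child == "BB")] <- (has_b(f) & has_b(m))[which(child == "BB")]
    ab <- which(child == "AB")
    ok[ab] <- ((has_a(f) & has_b(m)) | (has_b(f) & has_a(m)))[ab]
    bad <- which(!ok)
    if (length(bad)) {
      out[[length(out) + 1]] <- data.frame(
        sample_id = s$id[i], marker_id = panel$markers$id[bad],
        child = child[bad], father = f[bad], mother = m[bad],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(sample_id = character(), marker_id = character(),
               child = character(), father = character(),
               mother = character(), stringsAsFactors = FALSE)
}
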