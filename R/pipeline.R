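# End-to-end orchestration: simulate or load genotypes, repair the
# genetic map, run both scans, bridge, contrast, exclude known loci,
# rank, and write every stage's table plus a reproducibility manifest.

#' Build and validate a pipeline run configuration
#'
#' Either supply `ped`/`map` paths to analyse existing genotypes, or set
#' `simulate = TRUE` to generate a panel with [simulate_panel()]. All
#' referenced paths are checked at validation time, before any compute.
#'
#' @param outdir output directory (created if needed).
#' @param ped,map optional PLINK-style input paths.
#' @param annotation optional marker annotation TSV whose cM/MAF values
#'   override the `.map` file's.
#' @param known_loci BED file of known disease loci; `NULL` uses the
#'   packaged synthetic placeholder loci.
#' @param simulate generate the input panel instead of reading it.
#' @param sim a [sim_config()] used when `simulate = TRUE`.
#' @param hh an [hh_config()].
#' @param scan a [scan_config()].
#' @return a validated list of class `run_config`.
#' @export
run_config <- function(outdir, ped = NULL, map = NULL, annotation = NULL,
                       known_loci = NULL, simulate = FALSE,
                       sim = sim_config(), hh = hh_config(),
                       scan = scan_config()) {
  if (!simulate) {
    if (is.null(ped) || is.null(map)) {
      az_stop("supply ped and map paths, or set simulate = TRUE", "autozyg_config_error")
    }
    for (p in c(ped, map, annotation)) {
      if (!file.exists(p)) az_stop(sprintf("input file not found: %s", p),
                                   "autozyg_config_error")
    }
  }
  if (is.null(known_loci)) {
    known_loci <- system.file("extdata", "known_cmt_loci_synthetic.bed",
                              package = "autozyg")
  }
  if (!file.exists(known_loci)) {
    az_stop(sprintf("known-loci BED not found: %s", known_loci), "autozyg_config_error")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) az_stop(sprintf("cannot create output directory %s", outdir),
                                   "autozyg_config_error")
  structure(list(outdir = outdir, ped = ped, map = map,
                 annotation = annotation, known_loci = known_loci,
                 simulate = simulate, sim = sim, hh = hh, scan = scan),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Recognised keys mirror the arguments of [run_config()]; `sim`, `hh`
#' and `scan` may be nested maps of the corresponding config arguments
#' (the simulation marker map always comes from [default_marker_map()]
#' parameters `n_chrom`, `n_per_chrom`, `spacing_bp`, `cm_per_mb`).
#'
#' @param path YAML file path.
#' @return a validated `run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- hh <- scan <- NULL
  if (!is.null(y$sim)) {
    map_args <- y$sim[intersect(names(y$sim),
                                c("n_chrom", "n_per_chrom", "spacing_bp", "cm_per_mb"))]
    sim_args <- y$sim[intersect(names(y$sim), names(formals(sim_config)))]
    sim_args$markers <- do.call(default_marker_map, map_args)
    sim <- do.call(sim_config, sim_args)
  }
  if (!is.null(y$hh)) hh <- do.call(hh_config, y$hh)
  if (!is.null(y$scan)) scan <- do.call(scan_config, y$scan)
  args <- y[intersect(names(y), c("outdir", "ped", "map", "annotation",
                                  "known_loci", "simulate"))]
  if (!is.null(sim)) args$sim <- sim
  if (!is.null(hh)) args$hh <- hh
  if (!is.null(scan)) args$scan <- scan
  do.call(run_config, args)
}

write_tsv <- function(df, path) {
  # drop list-columns (per-marker allele vectors) from on-disk tables
  keep <- !vapply(df, is.list, TRUE)
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  path
}

#' Format runs as the seven-column candidate-interval report
#'
#' Layout: `SNPs, Chr, StartSNP, EndSNP, Start(bp), End(bp), Size(bp)`,
#' in descending order of consecutive-SNP count, with a `Contiguous`
#' annotation marking runs that [bridge_runs()] merged with a
#' neighbour. Numbers are written without thousands separators.
#'
#' @param runs run table from [shared_ibs_runs()].
#' @param merged optional merged-region table from [bridge_runs()], used
#'   for the contiguity flag.
#' @param path optional output path for the TSV.
#' @return the report data.frame, invisibly when `path` is given.
#' @export
make_table1_report <- function(runs, merged = NULL, path = NULL) {
  contiguous <- rep("", nrow(runs))
  if (!is.null(merged) && nrow(merged) > 0 && nrow(runs) > 0) {
    multi <- merged[merged$n_runs > 1, , drop = FALSE]
    for (i in seq_len(nrow(runs))) {
      hit <- multi$chrom == runs$chrom[i] &
        multi$start_idx <= runs$start_idx[i] & multi$end_idx >= runs$end_idx[i]
      if (any(hit)) contiguous[i] <- "yes"
    }
  }
  rep_df <- data.frame(
    SNPs = runs$n_snps, Chr = runs$chrom,
    StartSNP = runs$start_snp, EndSNP = runs$end_snp,
    `Start(bp)` = as.integer(runs$start_bp),
    `End(bp)` = as.integer(runs$end_bp),
    `Size(bp)` = as.integer(runs$size_bp),
    Contiguous = contiguous,
    check.names = FALSE, stringsAsFactors = FALSE)
  o <- order(-rep_df$SNPs, chrom_rank(rep_df$Chr), rep_df$`Start(bp)`)
  rep_df <- rep_df[o, , drop = FALSE]
  rownames(rep_df) <- NULL
  if (!is.null(path)) {
    write_tsv(rep_df, path)
    return(invisible(rep_df))
  }
  rep_df
}

run_stage <- function(name, timings, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    az_stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            "autozyg_stage_error")
  })
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(res = res, timings = timings)
}

#' Run the full homozygosity-mapping pipeline
#'
#' Stages, in order: input (simulate or read), map repair, HH scan,
#' known-locus exclusion, IBS run scan, bridging, unaffected contrast,
#' ranking, cross-method consensus, report. Every stage writes a TSV to
#' `config$outdir`; a JSON manifest records the package version, the
#' configuration, input checksums and stage timings. Stage tables are
#' pure functions of their inputs, so re-running a configuration
#' reproduces them byte for byte.
#'
#' @param config a [run_config()].
#' @param pedigree pedigree used when simulating (default
#'   [example_pedigree()]).
#' @return the manifest, invisibly; tables are on disk.
#' @export
run_pipeline <- function(config, pedigree = example_pedigree()) {
  stopifnot(inherits(config, "run_config"))
  outdir <- config$outdir
  timings <- list()
  truth <- NULL

  st <- run_stage("input", timings, {
    if (config$simulate) {
      sim <- simulate_panel(pedigree, config$sim)
      truth <- sim$truth  # assigns in run_pipeline's frame (promise eval env)
      write_panel(sim$panel, file.path(outdir, "panel.ped"),
                  file.path(outdir, "panel.map"))
      jsonlite::write_json(
        list(seed = config$sim$seed,
             causal_chrom = sim$truth$causal_chrom,
             causal_bp = sim$truth$causal_bp,
             detectable_bp = sim$truth$detectable_bp,
             n_perturbed = nrow(sim$truth$perturbation_log)),
        file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
      sim$panel
    } else {
      panel <- read_panel(config$ped, config$map)
      if (!is.null(config$annotation)) {
        ann <- read_annotation(config$annotation)
        i <- match(panel$markers$id, ann$id)
        panel$markers$cm[!is.na(i)] <- ann$cm[i[!is.na(i)]]
        panel$markers$maf[!is.na(i)] <- ann$maf[i[!is.na(i)]]
      }
      panel
    }
  })
  panel <- st$res; timings <- st$timings

  st <- run_stage("maprepair", timings, {
    repaired <- interpolate_cm(classify_invalid(panel$markers))
    write_tsv(repaired, file.path(outdir, "markers_repaired.tsv"))
    panel$markers$cm <- repaired$cm
    panel
  })
  panel <- st$res; timings <- st$timings

  aff <- affected_ids(panel)
  unaff <- unaffected_ids(panel)

  st <- run_stage("hh", timings, {
    rcch <- shared_rcch(panel, aff, config$hh)
    write_tsv(rcch, file.path(outdir, "rcch.tsv"))
    rcch
  })
  rcch <- st$res; timings <- st$timings

  st <- run_stage("exclude", timings, {
    loci <- read_known_loci(config$known_loci)
    excl <- test_known_loci(rcch, loci)
    write_tsv(excl, file.path(outdir, "exclusion.tsv"))
    excl
  })
  exclusion <- st$res; timings <- st$timings

  st <- run_stage("rohscan", timings, {
    runs <- shared_ibs_runs(panel, aff, config$scan)
    runs
  })
  runs <- st$res; timings <- st$timings

  st <- run_stage("bridge", timings, {
    merged <- bridge_runs(runs, panel)
    write_tsv(merged, file.path(outdir, "merged_regions.tsv"))
    merged
  })
  merged <- st$res; timings <- st$timings

  make_table1_report(runs, merged, file.path(outdir, "runs_report.tsv"))

  st <- run_stage("contrast", timings, {
    contrasted <- contrast_unaffected(merged, panel, unaff)
    write_tsv(contrasted, file.path(outdir, "contrast.tsv"))
    contrasted
  })
  contrasted <- st$res; timings <- st$timings

  st <- run_stage("rank", timings, {
    ranked <- rank_candidates(contrasted)
    if (!is.null(truth)) {
      ranked$truth_overlap <- ranked$chrom == truth$causal_chrom &
        ranked$start_bp <= truth$causal_bp & ranked$end_bp >= truth$causal_bp
    }
    write_tsv(ranked, file.path(outdir, "ranked_candidates.tsv"))
    ranked
  })
  ranked <- st$res; timings <- st$timings

  st <- run_stage("consensus", timings, {
    cons <- consensus(rcch, merged)
    write_tsv(cons, file.path(outdir, "consensus.tsv"))
    cons
  })
  timings <- st$timings

  inputs <- Filter(function(p) !is.null(p) && file.exists(p),
                   list(ped = config$ped, map = config$map,
                        annotation = config$annotation,
                        known_loci = config$known_loci))
  manifest <- list(
    tool = "autozyg",
    version = as.character(utils::packageVersion("autozyg")),
    config = list(
      simulate = config$simulate,
      seed = if (config$simulate) config$sim$seed else NULL,
      hh = unclass(config$hh), scan = unclass(config$scan),
      known_loci = config$known_loci),
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p))),
    n_markers = nrow(panel$markers),
    n_samples = nrow(panel$samples),
    n_affected = length(aff),
    n_rcch = nrow(rcch),
    n_loci_excluded = sum(exclusion$verdict == "EXCLUDED"),
    n_runs = nrow(runs),
    n_merged_regions = nrow(merged),
    top_candidate = if (nrow(ranked)) sprintf("%s:%d-%d", ranked$chrom[1],
                                              as.integer(ranked$start_bp[1]),
                                              as.integer(ranked$end_bp[1])) else NA,
    stage_seconds = timings)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
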