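# Reading, validating and writing pedigree genotype panels.
#
# Genotypes are held in platform-neutral AB coding: per marker the
# lexicographically smaller observed nucleotide is allele A, so "AA", "AB"
# and "BB" are the only genotype states besides missing. The Illumina
# TOP/BOT rule needs strand annotation that identical-by-state logic never
# uses, so any fixed per-marker bijection is adequate.

GENOTYPE_LEVELS <- c("AA", "AB", "BB")

#' Construct a genotype panel
#'
#' A genotype panel bundles an ordered marker table, a pedigree sample
#' table, and a markers x samples genotype call matrix in AB coding.
#'
#' @param markers data.frame with columns `id`, `chrom`, `pos_bp` and
#'   optionally `cm`, `maf`. Markers must be unique and, within each
#'   chromosome, strictly increasing in `pos_bp`.
#' @param samples data.frame with columns `id`, `father_id`, `mother_id`,
#'   `sex` ("male"/"female"/"unknown"), `status`
#'   ("affected"/"unaffected"/"unknown"). Parent ids, when not `NA`, must
#'   refer to samples in the same table and the pedigree must be acyclic.
#' @param calls character matrix (markers in rows, samples in columns) with
#'   entries in `"AA"`, `"AB"`, `"BB"` or `NA` for missing.
#' @return an object of class `genotype_panel`.
#' @export
genotype_panel <- function(markers, samples, calls) {
  markers <- as.data.frame(markers, stringsAsFactors = FALSE)
  samples <- as.data.frame(samples, stringsAsFactors = FALSE)
  if (is.null(samples$father_id)) samples$father_id <- NA_character_
  if (is.null(samples$mother_id)) samples$mother_id <- NA_character_
  if (is.null(samples$sex)) samples$sex <- "unknown"
  if (is.null(samples$status)) samples$status <- "unknown"
  if (is.null(markers$cm)) markers$cm <- NA_real_
  if (is.null(markers$maf)) markers$maf <- NA_real_
  calls <- as.matrix(calls)
  rownames(calls) <- markers$id
  colnames(calls) <- samples$id
  obj <- structure(list(markers = markers, samples = samples, calls = calls),
                   class = "genotype_panel")
  validate_panel(obj)
  obj
}

#' Validate a genotype panel
#'
#' Checks matrix dimensions, the closed genotype alphabet, marker
#' uniqueness and sort order, and pedigree consistency (parents present,
#' no individual its own ancestor).
#'
#' @param panel a `genotype_panel`.
#' @return the panel, invisibly; errors on violation.
#' @export
validate_panel <- function(panel) {
  m <- panel$markers; s <- panel$samples; g <- panel$calls
  if (nrow(g) != nrow(m) || ncol(g) != nrow(s)) {
    az_stop("call matrix dimensions do not match marker/sample counts",
            "autozyg_validation_error")
  }
  if (anyDuplicated(m$id)) {
    az_stop(sprintf("duplicate marker ids: %s",
                    paste(unique(m$id[duplicated(m$id)]), collapse = ", ")),
            "autozyg_validation_error")
  }
  if (anyDuplicated(s$id)) {
    az_stop("duplicate sample ids", "autozyg_validation_error")
  }
  if (any(m$pos_bp < 1)) {
    az_stop("marker positions must be >= 1", "autozyg_validation_error")
  }
  o <- order(chrom_rank(m$chrom), m$pos_bp)
  if (!identical(o, seq_len(nrow(m)))) {
    az_stop("markers are not sorted by (chromosome, position)",
            "autozyg_validation_error")
  }
  for (ch in unique(m$chrom)) {
    bp <- m$pos_bp[m$chrom == ch]
    if (any(diff(bp) <= 0)) {
      ids <- m$id[m$chrom == ch]
      bad <- which(diff(bp) <= 0)[1]
      az_stop(sprintf("markers %s and %s on chromosome %s share or invert bp order",
                      ids[bad], ids[bad + 1], ch), "autozyg_validation_error")
    }
  }
  bad <- !(g %in% GENOTYPE_LEVELS) & !is.na(g)
  if (any(bad)) {
    az_stop(sprintf("invalid genotype call '%s'", g[which(bad)[1]]),
            "autozyg_validation_error")
  }
  for (col in c("father_id", "mother_id")) {
    p <- s[[col]]
    miss <- !is.na(p) & !(p %in% s$id)
    if (any(miss)) {
      az_stop(sprintf("%s '%s' of sample '%s' is not in the pedigree",
                      col, p[miss][1], s$id[miss][1]),
              "autozyg_validation_error")
    }
  }
  # acyclicity via iterative topological peel
  remaining <- s$id
  parents <- cbind(s$father_id, s$mother_id)
  repeat {
    in_rem <- s$id %in% remaining
    has_parent_rem <- (parents[, 1] %in% remaining) | (parents[, 2] %in% remaining)
    leaves <- s$id[in_rem & !has_parent_rem]
    if (!length(leaves)) break
    remaining <- setdiff(remaining, leaves)
  }
  if (length(remaining)) {
    az_stop(sprintf("pedigree cycle involving: %s",
                    paste(remaining, collapse = ", ")),
            "autozyg_validation_error")
  }
  invisible(panel)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d markers x %d samples (%d affected)\n",
              nrow(x$markers), nrow(x$samples),
              sum(x$samples$status == "affected")))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$markers$chrom), collapse = ", ")))
  cat(sprintf("  missing calls: %d\n", sum(is.na(x$calls))))
  invisible(x)
}

#' Ids of affected / unaffected samples in a panel
#' @param panel a `genotype_panel`.
#' @return character vector of sample ids.
#' @export
affected_ids <- function(panel) panel$samples$id[panel$samples$status == "affected"]

#' @rdname affected_ids
#' @export
unaffected_ids <- function(panel) panel$samples$id[panel$samples$status == "unaffected"]

map_sex <- function(code) {
  v <- unname(c("1" = "male", "2" = "female")[as.character(code)])
  ifelse(is.na(v), "unknown", v)
}

map_status <- function(code) {
  v <- unname(c("2" = "affected", "1" = "unaffected")[as.character(code)])
  ifelse(is.na(v), "unknown", v)
}

split_ws <- function(lines) strsplit(trimws(lines), "[ \t]+")

#' Read a pedigree genotype panel from PLINK-style .ped/.map files
#'
#' The `.map` file has rows `(chrom, id, cM, bp)`; the `.ped` file has rows
#' `(famID, indID, father, mother, sex, phenotype)` followed by two allele
#' columns per marker, in `.map` row order. Allele pairs are mapped to AB
#' coding per marker (lexicographically smaller observed allele = A);
#' `0 0` (or any half-missing pair) becomes missing. Markers are sorted by
#' (chromosome, position). Phenotype coding is the PLINK convention:
#' 2 = affected, 1 = unaffected, anything else unknown.
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @return a `genotype_panel`.
#' @export
read_panel <- function(ped_path, map_path) {
  if (!file.exists(map_path)) az_stop(sprintf("map file not found: %s", map_path), "autozyg_io_error")
  if (!file.exists(ped_path)) az_stop(sprintf("ped file not found: %s", ped_path), "autozyg_io_error")

  map_rows <- split_ws(readLines(map_path))
  map_rows <- map_rows[vapply(map_rows, function(f) length(f) > 0 && nzchar(f[1]), TRUE)]
  nf <- vapply(map_rows, length, 0L)
  if (any(nf != 4)) {
    az_stop(sprintf("malformed .map row at line %d: expected 4 fields, got %d",
                    which(nf != 4)[1], nf[nf != 4][1]), "autozyg_parse_error")
  }
  mm <- do.call(rbind, map_rows)
  markers <- data.frame(
    id = mm[, 2], chrom = mm[, 1],
    pos_bp = suppressWarnings(as.numeric(mm[, 4])),
    cm = suppressWarnings(as.numeric(mm[, 3])),
    maf = NA_real_, stringsAsFactors = FALSE)
  if (anyNA(markers$pos_bp)) {
    az_stop(sprintf("malformed .map row at line %d: non-numeric bp",
                    which(is.na(markers$pos_bp))[1]), "autozyg_parse_error")
  }
  if (anyDuplicated(markers$id)) {
    az_stop(sprintf("duplicate marker id in .map: %s",
                    markers$id[duplicated(markers$id)][1]),
            "autozyg_validation_error")
  }
  n_mark <- nrow(markers)

  ped_rows <- split_ws(readLines(ped_path))
  ped_rows <- ped_rows[vapply(ped_rows, function(f) length(f) > 0 && nzchar(f[1]), TRUE)]
  expected <- 6 + 2 * n_mark
  nf <- vapply(ped_rows, length, 0L)
  if (any(nf != expected)) {
    i <- which(nf != expected)[1]
    az_stop(sprintf(".ped line %d has %d fields, expected %d", i, nf[i], expected),
            "autozyg_parse_error")
  }
  pm <- do.call(rbind, ped_rows)
  samples <- data.frame(
    id = pm[, 2],
    father_id = ifelse(pm[, 3] == "0", NA_character_, pm[, 3]),
    mother_id = ifelse(pm[, 4] == "0", NA_character_, pm[, 4]),
    sex = map_sex(pm[, 5]), status = map_status(pm[, 6]),
    family = pm[, 1], stringsAsFactors = FALSE)
  n_samp <- nrow(samples)

  a1 <- pm[, 6 + 2 * seq_len(n_mark) - 1, drop = FALSE]  # samples x markers
  a2 <- pm[, 6 + 2 * seq_len(n_mark), drop = FALSE]
  calls <- matrix(NA_character_, n_mark, n_samp)
  for (j in seq_len(n_mark)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    obs <- setdiff(unique(c(x1, x2)), "0")
    if (length(obs) > 2) {
      az_stop(sprintf("marker %s has more than two alleles: %s",
                      markers$id[j], paste(sort(obs), collapse = "/")),
              "autozyg_validation_error")
    }
    if (!length(obs)) next
    A <- sort(obs)[1]
    ok <- x1 != "0" & x2 != "0"
    nB <- (x1 != A) + (x2 != A)
    calls[j, ok] <- GENOTYPE_LEVELS[nB[ok] + 1]
  }

  o <- order(chrom_rank(markers$chrom), markers$pos_bp)
  genotype_panel(markers[o, , drop = FALSE], samples, calls[o, , drop = FALSE])
}

#' Write a genotype panel as PLINK-style .ped/.map files
#'
#' AB codes are emitted as literal alleles `A`/`B` (missing as `0 0`), so
#' re-reading reproduces the call matrix, marker order and pedigree fields
#' exactly. Centimorgan values that are `NA` are written as 0, the usual
#' placeholder in `.map` files.
#'
#' One caveat: AB coding is defined only up to the alleles actually
#' observed, so a marker at which allele A never appears (only BB calls)
#' reads back with the labels swapped (as AA). This relabelling is
#' irrelevant to every identity-by-state computation in the package.
#'
#' @param panel a `genotype_panel`.
#' @param ped_path,map_path output paths.
#' @return invisibly, the two paths.
#' @export
write_panel <- function(panel, ped_path, map_path) {
  validate_panel(panel)
  if (nrow(panel$samples) == 0) {
    az_stop("refusing to write a panel with no samples", "autozyg_io_error")
  }
  m <- panel$markers
  cm <- ifelse(is.na(m$cm), 0, m$cm)
  map_lines <- sprintf("%s\t%s\t%s\t%d", m$chrom, m$id,
                       format(cm, trim = TRUE, scientific = FALSE),
                       as.integer(m$pos_bp))
  writeLines(map_lines, map_path)

  s <- panel$samples
  fam <- s$family %||% rep("FAM1", nrow(s))
  sex_code <- c(male = "1", female = "2", unknown = "0")[s$sex]
  stat_code <- c(affected = "2", unaffected = "1", unknown = "0")[s$status]
  allele_txt <- c(AA = "A A", AB = "A B", BB = "B B")
  ped_lines <- vapply(seq_len(nrow(s)), function(i) {
    g <- panel$calls[, i]
    gt <- ifelse(is.na(g), "0 0", allele_txt[g])
    paste(c(fam[i], s$id[i],
            ifelse(is.na(s$father_id[i]), "0", s$father_id[i]),
            ifelse(is.na(s$mother_id[i]), "0", s$mother_id[i]),
            sex_code[i], stat_code[i], gt), collapse = " ")
  }, character(1))
  writeLines(ped_lines, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

ANNOT_SYNONYMS <- list(
  id = c("snp", "snp_id", "snpname", "snp_name", "id", "name", "marker"),
  chrom = c("chrom", "chr", "chromosome"),
  pos_bp = c("bp", "pos", "pos_bp", "position", "bp_position", "physical_position"),
  cm = c("cm", "cm_pos", "genetic_distance", "gendist", "cm_position"),
  maf = c("maf", "minor_allele_frequency", "freq")
)

#' Read a marker annotation table
#'
#' Expects a delimited text file with a header naming (in any casing /
#' common synonym) the SNP id, chromosome, bp position, centimorgan
#' position and minor allele frequency. Invalid centimorgan values (empty,
#' zero, non-monotone) are preserved as-is so that [classify_invalid()] and
#' [interpolate_cm()] can repair them explicitly rather than silently.
#'
#' @param path path to the annotation file (tab- or whitespace-delimited).
#' @return a marker data.frame (`id`, `chrom`, `pos_bp`, `cm`, `maf`)
#'   sorted by (chromosome, position).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) az_stop(sprintf("annotation file not found: %s", path), "autozyg_io_error")
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = c("NA", ""))
  nm <- tolower(gsub("[^a-z0-9]+", "_", tolower(names(df))))
  out <- list()
  for (canon in names(ANNOT_SYNONYMS)) {
    hit <- which(nm %in% ANNOT_SYNONYMS[[canon]])
    if (!length(hit)) {
      az_stop(sprintf("annotation schema error: no column for '%s' (header: %s)",
                      canon, paste(names(df), collapse = ", ")),
              "autozyg_schema_error")
    }
    out[[canon]] <- df[[hit[1]]]
  }
  markers <- data.frame(
    id = out$id, chrom = out$chrom,
    pos_bp = suppressWarnings(as.numeric(out$pos_bp)),
    cm = suppressWarnings(as.numeric(out$cm)),
    maf = suppressWarnings(as.numeric(out$maf)),
    stringsAsFactors = FALSE)
  if (anyNA(markers$pos_bp)) {
    az_stop("annotation rows with non-numeric bp position", "autozyg_parse_error")
  }
  if (anyDuplicated(markers$id)) {
    az_stop(sprintf("duplicate marker id in annotation: %s",
                    markers$id[duplicated(markers$id)][1]),
            "autozyg_validation_error")
  }
  key <- paste(markers$chrom, markers$pos_bp)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    ids <- markers$id[key == d]
    az_stop(sprintf("markers at identical position (%s): %s",
                    d, paste(ids, collapse = ", ")),
            "autozyg_ordering_error")
  }
  markers[order(chrom_rank(markers$chrom), markers$pos_bp), , drop = FALSE]
}

#' Write a marker annotation table
#'
#' @param markers marker data.frame as returned by [read_annotation()] or
#'   [interpolate_cm()]; any extra columns (e.g. `cm_repaired`) are kept.
#' @param path output path (tab-delimited, with header).
#' @return invisibly, `path`.
#' @export
write_annotation <- function(markers, path) {
  utils::write.table(markers, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
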