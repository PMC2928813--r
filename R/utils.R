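# Internal helpers shared across modules.

az_stop <- function(msg, class = "autozyg_error") {
  stop(errorCondition(msg, class = c(class, "autozyg_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Natural ordering rank for chromosome labels
#'
#' Autosomes sort numerically (1..22), then X, Y, XY, MT; any other label
#' sorts after those, alphabetically. Labels are opaque strings; a leading
#' "chr" prefix is ignored for ranking only.
#'
#' @param chrom character vector of chromosome labels.
#' @return numeric rank usable with [order()].
#' @keywords internal
chrom_rank <- function(chrom) {
  x <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  n <- suppressWarnings(as.numeric(x))
  special <- match(toupper(x), c("X", "Y", "XY", "MT", "M"))
  r <- ifelse(!is.na(n), n, ifelse(!is.na(special), 100 + special, NA_real_))
  unk <- is.na(r)
  if (any(unk)) {
    lev <- sort(unique(x[unk]))
    r[unk] <- 1000 + match(x[unk], lev)
  }
  r
}

# Round half away from zero (round() uses banker's rounding).
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Compact fingerprint used to detect that run tables and panels belong
# together without storing the whole panel alongside every result.
panel_signature <- function(panel) {
  list(
    n_markers = nrow(panel$markers),
    n_samples = nrow(panel$samples),
    first_marker = panel$markers$id[1],
    last_marker = panel$markers$id[nrow(panel$markers)],
    sample_ids = panel$samples$id
  )
}

same_panel <- function(sig_a, sig_b) {
  isTRUE(all.equal(sig_a, sig_b))
}

check_signature <- function(x, panel, what = "input") {
  sig <- attr(x, "panel_signature")
  if (is.null(sig)) return(invisible(TRUE))
  if (!same_panel(sig, panel_signature(panel))) {
    az_stop(sprintf("%s was computed from a different genotype panel", what),
            "autozyg_consistency_error")
  }
  invisible(TRUE)
}
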