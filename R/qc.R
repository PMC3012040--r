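#' Bisulfite conversion ratio of one aligned clone
#'
#' The conversion ratio is the fraction of non-CpG reference cytosines that
#' still read C in the clone: unconverted Cs outside CpG context divided by
#' all reference Cs outside CpG context covered by the alignment. It is a
#' treatment *failure* rate - lower is better; `1 - ratio` is the conversion
#' success. CpG-ness of a reference C is decided on the forward reference
#' strand; gap and clone-N columns are excluded from numerator and
#' denominator.
#'
#' @param aln A `clone_alignment` (orientation-resolved).
#' @param cpg_positions Integer positions of CpG Cs on the reference.
#' @return A list with `ratio` (NA when no non-CpG C is covered),
#'   `n_unconverted` and `n_nonCpG_C`.
#' @export
conversion_ratio <- function(aln, cpg_positions) {
  stopifnot(inherits(aln, "clone_alignment"))
  if (!nzchar(aln$aligned_ref)) {
    return(list(ratio = NA_real_, n_unconverted = 0L, n_nonCpG_C = 0L))
  }
  a <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1L]]
  b <- strsplit(aln$aligned_clone, "", fixed = TRUE)[[1L]]
  refpos <- ifelse(a != "-", aln$ref_start - 1L + cumsum(a != "-"), NA_integer_)
  denom <- a == "C" & !(refpos %in% cpg_positions) & b != "-" & b != "N"
  n_total <- sum(denom)
  n_unconv <- sum(denom & b == "C")
  list(ratio = if (n_total > 0L) n_unconv / n_total else NA_real_,
       n_unconverted = n_unconv, n_nonCpG_C = n_total)
}

#' Sequence identity rate from A/G/T-restricted counts
#'
#' @param matches,mismatches Non-negative counts from [local_align_agt()].
#' @return `matches / (matches + mismatches)`; NA when both counts are zero.
#' @export
identity_rate <- function(matches, mismatches) {
  if (matches < 0 || mismatches < 0) {
    abort("counts must be non-negative", class = "methclones_input_error")
  }
  if (matches + mismatches == 0) return(NA_real_)
  matches / (matches + mismatches)
}

#' Per-clone quality control report
#'
#' Computes the two QC statistics for every aligned clone - the bisulfite
#' conversion ratio (from the global alignment) and the A/G/T-restricted
#' identity rate (from a local alignment of the oriented clone) - and applies
#' the pass/fail gates.
#'
#' @param alignments Tibble from [align_clones()].
#' @param ref A `reference_sequence` from [find_cpg_sites()].
#' @param scheme [subst_scheme()] used for the identity local alignment.
#' @inheritParams apply_gates
#' @return A tibble, one row per clone: `clone_id`, `orientation`, `score`,
#'   `conversion_ratio`, `conversion_success`, `n_unconverted`,
#'   `n_nonCpG_C`, `identity_rate`, `n_match`, `n_mismatch`, `flagged`,
#'   `passed`, `failed_gates`.
#' @export
qc_clones <- function(alignments, ref, scheme = subst_scheme(),
                      max_conversion_ratio = 0.1, min_identity = 0.8,
                      min_score = -Inf) {
  stopifnot(inherits(ref, "reference_sequence"))
  rows <- purrr::map(alignments$alignment, function(a) {
    cr <- conversion_ratio(a, ref$cpg_positions)
    oriented <- gsub("-", "", a$aligned_clone, fixed = TRUE)
    loc <- if (nzchar(oriented)) {
      local_align_agt(ref$bases, oriented, scheme)
    } else {
      list(matches = 0L, mismatches = 0L)
    }
    tibble(
      clone_id = a$clone_id,
      orientation = a$orientation,
      score = a$score,
      conversion_ratio = cr$ratio,
      conversion_success = 1 - cr$ratio,
      n_unconverted = cr$n_unconverted,
      n_nonCpG_C = cr$n_nonCpG_C,
      identity_rate = identity_rate(loc$matches, loc$mismatches),
      n_match = loc$matches,
      n_mismatch = loc$mismatches,
      flagged = a$flagged
    )
  })
  reports <- dplyr::bind_rows(rows)
  apply_gates(reports, max_conversion_ratio = max_conversion_ratio,
              min_identity = min_identity, min_score = min_score)
}

#' Apply pass/fail gates to QC reports
#'
#' Adds `passed` and `failed_gates` columns; every failing clone names the
#' specific gate(s) it violated. A clone with an undefined conversion ratio
#' (no non-CpG C covered) or an undefined identity rate fails with an
#' `*_undefined` marker, as does an unalignable (`flagged`) clone.
#'
#' @param reports Tibble of per-clone QC rows (see [qc_clones()]).
#' @param max_conversion_ratio Highest acceptable conversion failure rate
#'   (default 0.1).
#' @param min_identity Lowest acceptable identity rate (default 0.8).
#' @param min_score Lowest acceptable alignment score (default `-Inf`).
#' @return `reports` with `passed` (logical) and `failed_gates` (character,
#'   `""` for passing clones) columns.
#' @export
apply_gates <- function(reports, max_conversion_ratio = 0.1,
                        min_identity = 0.8, min_score = -Inf) {
  gates <- purrr::pmap_chr(
    list(reports$conversion_ratio, reports$identity_rate, reports$score,
         reports$flagged %||% FALSE),
    function(cr, idr, sc, fl) {
      bad <- character()
      if (isTRUE(fl)) bad <- c(bad, "unalignable")
      if (is.na(cr)) bad <- c(bad, "conversion_undefined")
      else if (cr > max_conversion_ratio) bad <- c(bad, "conversion_ratio")
      if (is.na(idr)) bad <- c(bad, "identity_undefined")
      else if (idr < min_identity) bad <- c(bad, "identity_rate")
      if (sc < min_score) bad <- c(bad, "score")
      paste(bad, collapse = ",")
    }
  )
  reports$passed <- !nzchar(gates)
  reports$failed_gates <- gates
  reports
}

#' Export a QC report
#'
#' @param reports Tibble from [qc_clones()].
#' @param tsv Optional TSV path (one row per clone).
#' @param txt Optional path for a human-readable summary.
#' @return `reports`, invisibly.
#' @export
export_qc <- function(reports, tsv = NULL, txt = NULL) {
  if (!is.null(tsv)) write_tsv_plain(reports, tsv)
  if (!is.null(txt)) {
    lines <- c(
      sprintf("QC summary: %d clone(s), %d passed, %d failed",
              nrow(reports), sum(reports$passed), sum(!reports$passed)),
      sprintf("  mean conversion success: %s",
              format(mean(reports$conversion_success, na.rm = TRUE), digits = 4)),
      sprintf("  mean identity rate:      %s",
              format(mean(reports$identity_rate, na.rm = TRUE), digits = 4)),
      if (any(!reports$passed)) c(
        "  failing clones:",
        sprintf("    %s: %s", reports$clone_id[!reports$passed],
                reports$failed_gates[!reports$passed])
      )
    )
    writeLines(lines, txt)
  }
  invisible(reports)
}
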