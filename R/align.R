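IUPAC_ALPHA <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                 "V", "H", "D", "B", "N")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"), S = c("C", "G"),
  Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"), D = c("A", "G", "T"),
  B = c("C", "G", "T"), N = c("A", "C", "G", "T")
)

#' Bisulfite-tolerant substitution scheme
#'
#' Scoring parameters for clone-versus-reference alignment. The scheme
#' tolerates the hallmark of bisulfite conversion: a clone T aligned to a
#' reference C scores `bisulfite_TC` rather than a mismatch. The tolerance is
#' directional; a clone C against a reference T is an ordinary mismatch,
#' because conversion turns C into T on the clone strand only. `N` scores 0
#' against anything; other IUPAC ambiguity codes score a match when the two
#' base sets intersect.
#'
#' @param match Score for identical (or set-compatible) bases. Default +1.
#' @param mismatch Score for incompatible bases. Default -1.
#' @param bisulfite_TC Score for clone T vs reference C; must be at least
#'   `mismatch`. Default equals `match` (full tolerance).
#' @param gap_open Score of the first base of a gap (<= 0). Default -2.
#' @param gap_extend Score of each further gap base (<= 0). Default -1.
#' @return An object of class `subst_scheme`.
#' @examples
#' subst_scheme()
#' subst_scheme(bisulfite_TC = 0.5)
#' @export
subst_scheme <- function(match = 1, mismatch = -1, bisulfite_TC = match,
                         gap_open = -2, gap_extend = -1) {
  if (match <= mismatch) {
    abort("`match` must exceed `mismatch`", class = "methclones_input_error")
  }
  if (bisulfite_TC < mismatch) {
    abort("`bisulfite_TC` must not be below `mismatch`",
          class = "methclones_input_error")
  }
  if (gap_open > 0 || gap_extend > 0) {
    abort("gap penalties must be <= 0", class = "methclones_input_error")
  }
  structure(
    list(match = match, mismatch = mismatch, bisulfite_TC = bisulfite_TC,
         gap_open = gap_open, gap_extend = gap_extend),
    class = "subst_scheme"
  )
}

#' @export
print.subst_scheme <- function(x, ...) {
  cat("<subst_scheme>  match ", x$match, ", mismatch ", x$mismatch,
      ", clone-T/ref-C ", x$bisulfite_TC,
      ", gap open/extend ", x$gap_open, "/", x$gap_extend, "\n", sep = "")
  invisible(x)
}

# 15x15 score matrix indexed [ref, clone] (asymmetric: T/C tolerance is
# directional)
scheme_matrix <- function(scheme) {
  k <- length(IUPAC_ALPHA)
  S <- matrix(scheme$mismatch, k, k, dimnames = list(IUPAC_ALPHA, IUPAC_ALPHA))
  for (a in IUPAC_ALPHA) {
    for (b in IUPAC_ALPHA) {
      if (a == "N" || b == "N") {
        S[a, b] <- 0
      } else if (length(intersect(IUPAC_SETS[[a]], IUPAC_SETS[[b]])) > 0L) {
        S[a, b] <- scheme$match
      } else if ("C" %in% IUPAC_SETS[[a]] && "T" %in% IUPAC_SETS[[b]]) {
        S[a, b] <- scheme$bisulfite_TC
      }
    }
  }
  S
}

encode_bases <- function(x, what = "sequence") {
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
    abort(paste0(what, " must be a non-empty string"),
          class = "methclones_input_error")
  }
  chars <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  codes <- match(chars, IUPAC_ALPHA)
  if (anyNA(codes)) {
    bad <- chars[which(is.na(codes))[1L]]
    abort(paste0("non-IUPAC character '", bad, "' in ", what),
          class = "methclones_input_error")
  }
  codes - 1L
}

ops_to_strings <- function(ops, ref_chars, clone_chars) {
  if (!nzchar(ops)) {
    return(list(ref = "", clone = ""))
  }
  op <- strsplit(ops, "", fixed = TRUE)[[1L]]
  ar <- character(length(op))
  ac <- character(length(op))
  i <- 0L; j <- 0L
  for (k in seq_along(op)) {
    if (op[k] == "0") {
      i <- i + 1L; j <- j + 1L
      ar[k] <- ref_chars[i]; ac[k] <- clone_chars[j]
    } else if (op[k] == "1") {
      i <- i + 1L
      ar[k] <- ref_chars[i]; ac[k] <- "-"
    } else {
      j <- j + 1L
      ar[k] <- "-"; ac[k] <- clone_chars[j]
    }
  }
  list(ref = paste(ar, collapse = ""), clone = paste(ac, collapse = ""))
}

new_clone_alignment <- function(clone_id, orientation, score,
                                aligned_ref, aligned_clone,
                                ref_start, ref_end, flagged = FALSE) {
  structure(
    list(clone_id = clone_id, orientation = orientation, score = score,
         aligned_ref = aligned_ref, aligned_clone = aligned_clone,
         ref_start = ref_start, ref_end = ref_end, flagged = flagged),
    class = "clone_alignment"
  )
}

#' @export
print.clone_alignment <- function(x, ...) {
  cat("<clone_alignment> ", x$clone_id, "  orientation=", x$orientation,
      "  score=", format(x$score), "  ref ", x$ref_start, "..", x$ref_end,
      if (isTRUE(x$flagged)) "  [FLAGGED]" else "", "\n", sep = "")
  w <- 60L
  n <- nchar(x$aligned_ref)
  for (s in seq(1L, n, by = w)) {
    e <- min(s + w - 1L, n)
    cat("  ref   ", substring(x$aligned_ref, s, e), "\n",
        "  clone ", substring(x$aligned_clone, s, e), "\n", sep = "")
  }
  invisible(x)
}

# trim terminal gap columns so ref_start/ref_end describe the region the
# clone actually covers; interior gaps are kept
trim_terminal_gaps <- function(ar, ac) {
  a <- strsplit(ar, "", fixed = TRUE)[[1L]]
  b <- strsplit(ac, "", fixed = TRUE)[[1L]]
  keep <- a != "-" & b != "-"
  if (!any(keep)) {
    return(list(ref = "", clone = "", ref_offset = 0L, ref_len = 0L))
  }
  from <- which(keep)[1L]
  to <- tail(which(keep), 1L)
  ref_before <- sum(a[seq_len(from - 1L)] != "-")
  ref_in <- sum(a[from:to] != "-")
  list(ref = paste(a[from:to], collapse = ""),
       clone = paste(b[from:to], collapse = ""),
       ref_offset = ref_before, ref_len = ref_in)
}

#' Global (Needleman-Wunsch) alignment of a clone to the reference
#'
#' Optimal global alignment under a bisulfite-tolerant [subst_scheme()] with
#' affine gaps and deterministic traceback (diagonal preferred over a gap in
#' the clone, preferred over a gap in the reference). The reported
#' `ref_start`/`ref_end` give the 1-based, closed reference interval covered
#' by the clone (terminal gap columns are trimmed from the reported
#' alignment); the score is that of the full global alignment.
#'
#' @param ref Reference bases (string).
#' @param clone Clone bases (string).
#' @param scheme A [subst_scheme()].
#' @param clone_id Label stored in the result.
#' @return A `clone_alignment` object with fields `clone_id`, `orientation`,
#'   `score`, `aligned_ref`, `aligned_clone`, `ref_start`, `ref_end`,
#'   `flagged`.
#' @examples
#' needleman_wunsch("ACGT", "AGT", subst_scheme())
#' @export
needleman_wunsch <- function(ref, clone, scheme = subst_scheme(),
                             clone_id = "clone") {
  rc <- encode_bases(ref, "ref")
  cc <- encode_bases(clone, "clone")
  S <- scheme_matrix(scheme)
  res <- cpp_align_global(rc, cc, S, scheme$gap_open, scheme$gap_extend)
  refu <- toupper(ref)
  cloneu <- toupper(clone)
  strs <- ops_to_strings(res$ops,
                         strsplit(refu, "", fixed = TRUE)[[1L]],
                         strsplit(cloneu, "", fixed = TRUE)[[1L]])
  tr <- trim_terminal_gaps(strs$ref, strs$clone)
  new_clone_alignment(clone_id, "identity", res$score, tr$ref, tr$clone,
                      ref_start = tr$ref_offset + 1L,
                      ref_end = tr$ref_offset + tr$ref_len)
}

orientation_variants <- function(clone) {
  d <- Biostrings::DNAString(toupper(clone))
  list(
    identity = as.character(d),
    reverse = as.character(Biostrings::reverse(d)),
    complement = as.character(Biostrings::complement(d)),
    reverse_complement = as.character(Biostrings::reverseComplement(d))
  )
}

#' Resolve clone orientation by alignment score (alignment control)
#'
#' Sequencer output may be reversed, complemented or reverse-complemented
#' relative to the reference. All four orientation candidates (including the
#' clone as given, so correctly oriented input is never transformed) are
#' globally aligned and the highest-scoring candidate is returned with its
#' orientation recorded. Ties resolve in the order identity, reverse,
#' complement, reverse-complement. If all four scores are equal and at or
#' below `floor` the clone is unalignable and the result is flagged.
#'
#' @inheritParams needleman_wunsch
#' @param floor Score at or below which four equal candidates are considered
#'   unalignable (default 0).
#' @return A `clone_alignment` for the winning orientation; the aligned clone
#'   is the transformed (forward-oriented) sequence.
#' @export
orient_clone <- function(ref, clone, scheme = subst_scheme(),
                         clone_id = "clone", floor = 0) {
  variants <- orientation_variants(clone)
  alns <- lapply(names(variants), function(o) {
    a <- needleman_wunsch(ref, variants[[o]], scheme, clone_id)
    a$orientation <- o
    a
  })
  scores <- vapply(alns, `[[`, numeric(1), "score")
  best <- alns[[which.max(scores)]]
  if (length(unique(scores)) == 1L && scores[1L] <= floor) {
    best$flagged <- TRUE
    warn(paste0("clone '", clone_id, "' is unalignable: all four orientation ",
                "candidates score ", format(scores[1L])))
  }
  best
}

#' Align a batch of clones with orientation control
#'
#' Runs [orient_clone()] for every clone and returns a tibble, one row per
#' clone, with the full `clone_alignment` objects in a list-column.
#'
#' @param clones Tibble with columns `id`, `bases` (as from [read_fasta()]).
#' @param ref Reference bases (string) or a single-row tibble from
#'   [read_fasta()].
#' @param scheme A [subst_scheme()].
#' @param floor Passed to [orient_clone()].
#' @return A tibble with columns `clone_id`, `orientation`, `score`,
#'   `ref_start`, `ref_end`, `flagged`, `alignment` (list-column).
#' @export
align_clones <- function(clones, ref, scheme = subst_scheme(), floor = 0) {
  ref <- ref_bases(ref)
  alns <- purrr::map2(clones$bases, clones$id,
                      ~orient_clone(ref, .x, scheme, clone_id = .y,
                                    floor = floor))
  tibble(
    clone_id = clones$id,
    orientation = vapply(alns, `[[`, character(1), "orientation"),
    score = vapply(alns, `[[`, numeric(1), "score"),
    ref_start = vapply(alns, function(a) as.integer(a$ref_start), integer(1)),
    ref_end = vapply(alns, function(a) as.integer(a$ref_end), integer(1)),
    flagged = vapply(alns, `[[`, logical(1), "flagged"),
    alignment = alns
  )
}

ref_bases <- function(ref) {
  if (is.character(ref) && length(ref) == 1L) return(toupper(ref))
  if (is.data.frame(ref)) {
    if (nrow(ref) != 1L) {
      abort("reference table must contain exactly one sequence",
            class = "methclones_input_error")
    }
    return(toupper(ref$bases))
  }
  if (inherits(ref, "reference_sequence")) return(ref$bases)
  abort("cannot interpret `ref` as a reference sequence",
        class = "methclones_input_error")
}

#' A/G/T-restricted local alignment identity counts
#'
#' Smith-Waterman local alignment of an orientation-resolved clone against
#' the reference under the same bisulfite-tolerant scheme, followed by a
#' match/mismatch tally restricted to the three bases A, G and T: alignment
#' columns where the reference base is C are excluded (their C/T state
#' reflects bisulfite chemistry, not sequence identity), as are gap columns.
#'
#' @inheritParams needleman_wunsch
#' @return A list with `matches`, `mismatches`, `score`, `ref_start`,
#'   `ref_end`. An empty local alignment yields (0, 0) with a warning.
#' @export
local_align_agt <- function(ref, clone, scheme = subst_scheme()) {
  rc <- encode_bases(ref, "ref")
  cc <- encode_bases(clone, "clone")
  S <- scheme_matrix(scheme)
  res <- cpp_align_local(rc, cc, S, scheme$gap_open, scheme$gap_extend)
  if (!nzchar(res$ops)) {
    warn("empty local alignment: no positive-scoring overlap")
    return(list(matches = 0L, mismatches = 0L, score = res$score,
                ref_start = NA_integer_, ref_end = NA_integer_))
  }
  strs <- ops_to_strings(res$ops,
                         strsplit(toupper(ref), "", fixed = TRUE)[[1L]][
                           seq(res$ref_start, res$ref_end)],
                         strsplit(toupper(clone), "", fixed = TRUE)[[1L]][
                           seq(res$clone_start, res$clone_end)])
  a <- strsplit(strs$ref, "", fixed = TRUE)[[1L]]
  b <- strsplit(strs$clone, "", fixed = TRUE)[[1L]]
  use <- a != "-" & b != "-" & a != "C"
  list(matches = sum(a[use] == b[use]),
       mismatches = sum(a[use] != b[use]),
       score = res$score,
       ref_start = res$ref_start, ref_end = res$ref_end)
}

#' Export alignments as TSV and pairwise FASTA
#'
#' @param alignments Tibble from [align_clones()].
#' @param tsv Optional path for a tabular summary (clone_id, orientation,
#'   score, ref_start, ref_end, flagged).
#' @param fasta Optional path for gapped pairwise FASTA (two records per
#'   clone: `<id>|ref` and `<id>|clone`).
#' @return `alignments`, invisibly.
#' @export
export_alignments <- function(alignments, tsv = NULL, fasta = NULL) {
  if (!is.null(tsv)) {
    write_tsv_plain(alignments[setdiff(names(alignments), "alignment")], tsv)
  }
  if (!is.null(fasta)) {
    lines <- unlist(lapply(alignments$alignment, function(a) {
      c(paste0(">", a$clone_id, "|ref ", a$ref_start, "..", a$ref_end),
        a$aligned_ref,
        paste0(">", a$clone_id, "|clone orientation=", a$orientation,
               " score=", format(a$score)),
        a$aligned_clone)
    }))
    writeLines(lines, fasta)
  }
  invisible(alignments)
}

write_tsv_plain <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
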