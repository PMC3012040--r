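#' Locate CpG sites on a reference sequence
#'
#' Scans the forward strand for CG dinucleotides and records the 1-based
#' position of each C.
#'
#' @param ref A single-row tibble from [read_fasta()], or a string of bases.
#' @param id Reference id, used when `ref` is a bare string.
#' @return A `reference_sequence` object: fields `id`, `bases`,
#'   `cpg_positions` (strictly increasing integer vector).
#' @examples
#' find_cpg_sites("ACGTCG", id = "r")$cpg_positions  # 2, 5
#' @export
find_cpg_sites <- function(ref, id = "reference") {
  if (is.data.frame(ref)) {
    if (nrow(ref) != 1L) {
      abort("reference table must contain exactly one sequence",
            class = "methclones_input_error")
    }
    id <- ref$id
    ref <- ref$bases
  }
  bases <- toupper(ref)
  if (!nzchar(bases)) {
    abort("reference must be non-empty", class = "methclones_input_error")
  }
  hits <- gregexpr("(?=CG)", bases, perl = TRUE)[[1L]]
  pos <- if (hits[1L] == -1L) integer(0) else as.integer(hits)
  structure(list(id = id, bases = bases, cpg_positions = pos),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat("<reference_sequence> ", x$id, "  ", nchar(x$bases), " bp, ",
      length(x$cpg_positions), " CpG site(s)",
      if (length(x$cpg_positions)) paste0(" at ",
        paste(head(x$cpg_positions, 10L), collapse = ", "),
        if (length(x$cpg_positions) > 10L) ", ..." else ""),
      "\n", sep = "")
  invisible(x)
}

#' Call methylation states for one aligned clone
#'
#' For each reference CpG position covered by the alignment, a clone C means
#' the cytosine survived bisulfite treatment (methylated, 1) and a clone T
#' means it was converted (unmethylated, 0). A gap, an N, or any other base
#' at the CpG column is evidence of sequencing trouble, not of methylation
#' state, and yields NA; CpG positions outside the aligned span are NA.
#'
#' @param aln A `clone_alignment` (orientation-resolved, QC-passed).
#' @param ref A `reference_sequence` from [find_cpg_sites()].
#' @return Named numeric vector over `ref$cpg_positions` with values 1, 0 or
#'   NA.
#' @export
call_methylation <- function(aln, ref) {
  stopifnot(inherits(aln, "clone_alignment"), inherits(ref, "reference_sequence"))
  pos <- ref$cpg_positions
  out <- rep(NA_real_, length(pos))
  names(out) <- pos
  if (length(pos) == 0L || !nzchar(aln$aligned_ref)) return(out)
  a <- strsplit(aln$aligned_ref, "", fixed = TRUE)[[1L]]
  b <- strsplit(aln$aligned_clone, "", fixed = TRUE)[[1L]]
  refpos <- ifelse(a != "-", aln$ref_start - 1L + cumsum(a != "-"), NA_integer_)
  col_of <- match(pos, refpos)
  covered <- pos >= aln$ref_start & pos <= aln$ref_end & !is.na(col_of)
  if (any(!is.na(col_of) & covered)) {
    cb <- b[col_of[covered]]
    out[covered] <- ifelse(cb == "C", 1, ifelse(cb == "T", 0, NA_real_))
  }
  out
}

#' Construct a clone-by-CpG methylation dataset
#'
#' The central container: a ternary matrix (1 methylated, 0 unmethylated, NA
#' missing) with clones as rows and CpG positions as columns, plus per-clone
#' aligned spans.
#'
#' @param calls Numeric matrix of 1/0/NA, clones in rows (rownames used as
#'   clone ids when present).
#' @param cpg_positions Integer vector of 1-based reference positions, one
#'   per matrix column, strictly increasing.
#' @param clone_ids Optional character vector of row ids.
#' @param spans Optional tibble/data frame with columns `clone_id`,
#'   `ref_start`, `ref_end`; defaults to full coverage of the CpG range.
#' @param ref_id Reference identifier carried along.
#' @return A `meth_set` object.
#' @export
meth_set <- function(calls, cpg_positions, clone_ids = NULL, spans = NULL,
                     ref_id = "reference") {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "double"
  cpg_positions <- as.integer(cpg_positions)
  if (ncol(calls) != length(cpg_positions)) {
    abort("number of matrix columns must equal number of CpG positions",
          class = "methclones_input_error")
  }
  if (is.unsorted(cpg_positions, strictly = TRUE)) {
    abort("`cpg_positions` must be strictly increasing",
          class = "methclones_input_error")
  }
  if (!all(calls %in% c(0, 1) | is.na(calls))) {
    abort("methylation calls must be 0, 1 or NA",
          class = "methclones_input_error")
  }
  if (is.null(clone_ids)) {
    clone_ids <- rownames(calls) %||% paste0("clone", seq_len(nrow(calls)))
  }
  if (anyDuplicated(clone_ids)) {
    abort("duplicate clone ids", class = "methclones_input_error")
  }
  dimnames(calls) <- list(clone_ids, cpg_positions)
  if (is.null(spans)) {
    spans <- tibble(clone_id = clone_ids,
                    ref_start = if (length(cpg_positions)) min(cpg_positions) else 1L,
                    ref_end = if (length(cpg_positions)) max(cpg_positions) + 1L else 1L)
  } else {
    spans <- as_tibble(spans)[c("clone_id", "ref_start", "ref_end")]
    if (!identical(as.character(spans$clone_id), as.character(clone_ids))) {
      abort("`spans` must have one row per clone, in clone order",
            class = "methclones_input_error")
    }
  }
  # span invariant: positions outside a clone's span carry no call
  for (i in seq_len(nrow(calls))) {
    outside <- cpg_positions < spans$ref_start[i] | cpg_positions > spans$ref_end[i]
    if (any(outside & !is.na(calls[i, ]))) {
      abort(paste0("clone '", clone_ids[i],
                   "' has calls outside its aligned span"),
            class = "methclones_input_error")
    }
  }
  structure(list(clone_ids = as.character(clone_ids),
                 cpg_positions = cpg_positions,
                 calls = calls, spans = spans, ref_id = ref_id),
            class = "meth_set")
}

#' @export
print.meth_set <- function(x, ...) {
  cat("<meth_set> ", length(x$clone_ids), " clone(s) x ",
      length(x$cpg_positions), " CpG site(s)  [ref: ", x$ref_id, "]\n", sep = "")
  if (length(x$clone_ids) && length(x$cpg_positions)) {
    print(x$calls[seq_len(min(8L, nrow(x$calls))), , drop = FALSE])
    if (nrow(x$calls) > 8L) cat("  ... ", nrow(x$calls) - 8L, " more clone(s)\n")
  }
  invisible(x)
}

#' @export
dim.meth_set <- function(x) dim(x$calls)

#' @export
as_tibble.meth_set <- function(x, ...) {
  if (length(x$clone_ids) == 0L) {
    return(tibble(clone_id = character(), position = integer(),
                  call = double()))
  }
  tibble(
    clone_id = rep(x$clone_ids, times = length(x$cpg_positions)),
    position = rep(x$cpg_positions, each = length(x$clone_ids)),
    call = as.vector(x$calls)
  )
}

#' Assemble a methylation dataset from clone alignments
#'
#' Calls methylation per clone with [call_methylation()] and stacks the rows
#' into a [meth_set()], preserving input clone order.
#'
#' @param alignments Tibble from [align_clones()] (only rows that passed QC
#'   should be supplied), or a list of `clone_alignment` objects.
#' @param ref A `reference_sequence` from [find_cpg_sites()].
#' @return A `meth_set`.
#' @export
assemble_dataset <- function(alignments, ref) {
  stopifnot(inherits(ref, "reference_sequence"))
  alns <- if (is.data.frame(alignments)) alignments$alignment else alignments
  ids <- vapply(alns, `[[`, character(1), "clone_id")
  rows <- lapply(alns, call_methylation, ref = ref)
  calls <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0L, length(ref$cpg_positions))
  spans <- tibble(
    clone_id = ids,
    ref_start = vapply(alns, function(a) as.integer(a$ref_start), integer(1)),
    ref_end = vapply(alns, function(a) as.integer(a$ref_end), integer(1))
  )
  if (length(ids) == 0L) {
    spans <- tibble(clone_id = character(), ref_start = integer(),
                    ref_end = integer())
    return(structure(list(clone_ids = character(),
                          cpg_positions = ref$cpg_positions,
                          calls = calls, spans = spans, ref_id = ref$id),
                     class = "meth_set"))
  }
  meth_set(calls, ref$cpg_positions, clone_ids = ids, spans = spans,
           ref_id = ref$id)
}

METH_JSON_SCHEMA <- "methclones/meth_set/1"

#' Serialize / restore a methylation dataset as JSON
#'
#' A self-describing, versioned JSON container holding clone ids, CpG
#' positions, aligned spans and the ternary call matrix (row-major, `null`
#' for missing). `read_meth_json(write_meth_json(ds, p))` restores the
#' dataset field for field.
#'
#' @param ds A `meth_set`.
#' @param path Output (input) file path.
#' @return `path` invisibly (`write`); a `meth_set` (`read`).
#' @export
write_meth_json <- function(ds, path) {
  stopifnot(inherits(ds, "meth_set"))
  obj <- list(
    schema = METH_JSON_SCHEMA,
    ref_id = ds$ref_id,
    clone_ids = ds$clone_ids,
    cpg_positions = ds$cpg_positions,
    spans = ds$spans,
    calls = unname(apply(ds$calls, 1L, as.list, simplify = FALSE))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_meth_json
#' @export
read_meth_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema, METH_JSON_SCHEMA)) {
    abort(paste0(path, ": not a methclones dataset (schema '",
                 obj$schema %||% "?", "')"),
          class = "methclones_format_error")
  }
  clone_ids <- unlist(obj$clone_ids) %||% character()
  pos <- as.integer(unlist(obj$cpg_positions) %||% integer())
  calls <- matrix(NA_real_, length(clone_ids), length(pos))
  for (i in seq_along(obj$calls)) {
    row <- obj$calls[[i]]
    calls[i, ] <- vapply(row, function(v) if (is.null(v)) NA_real_ else
      as.numeric(v), numeric(1))
  }
  spans <- tibble(
    clone_id = vapply(obj$spans, function(s) as.character(s$clone_id), character(1)),
    ref_start = vapply(obj$spans, function(s) as.integer(s$ref_start), integer(1)),
    ref_end = vapply(obj$spans, function(s) as.integer(s$ref_end), integer(1))
  )
  if (length(clone_ids) == 0L) {
    return(structure(list(clone_ids = character(), cpg_positions = pos,
                          calls = calls, spans = spans,
                          ref_id = obj$ref_id %||% "reference"),
                     class = "meth_set"))
  }
  meth_set(calls, pos, clone_ids = clone_ids, spans = spans,
           ref_id = obj$ref_id %||% "reference")
}

#' Export the call matrix as TSV
#'
#' Header row carries the CpG positions; first column the clone ids; cells
#' are 1, 0 or NA.
#'
#' @param ds A `meth_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_meth_matrix <- function(ds, path) {
  df <- data.frame(clone_id = ds$clone_ids, ds$calls, check.names = FALSE)
  write_tsv_plain(df, path)
}
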