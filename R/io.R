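#' Read sequences from a FASTA file
#'
#' Reads a (multi-)FASTA file of DNA sequences into a tibble with one row per
#' record. Bases are uppercase-normalised; soft-masking is not preserved.
#' Sequence ids (the first whitespace-delimited token of each header) must be
#' unique within the file.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` (character), `bases` (character, IUPAC
#'   uppercase) and `source_file` (character), rows in file order.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">c1", "ACGT", ">c2", "acgRn"), fa)
#' read_fasta(fa)
#' @seealso [write_fasta()], [read_gff_sequences()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "methclones_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  validate_fasta_lines(lines, path)
  set <- Biostrings::readDNAStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    abort(paste0("duplicate sequence id(s) in ", path, ": ",
                 paste(dup, collapse = ", ")),
          class = "methclones_format_error")
  }
  tibble(
    id = ids,
    bases = unname(toupper(as.character(set))),
    source_file = path
  )
}

# structural pre-check so format errors can name the offending line, which
# Biostrings' parser does not report
validate_fasta_lines <- function(lines, path) {
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    abort(paste0("empty FASTA file: ", path), class = "methclones_format_error")
  }
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    abort(paste0(path, " line ", first,
                 ": expected a '>' header before sequence data"),
          class = "methclones_format_error")
  }
  iupac <- "^[ACGTUMRWSYKVHDBNacgtumrwsykvhdbn]*$"
  for (i in nonblank) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (!nzchar(trimws(substring(ln, 2L)))) {
        abort(paste0(path, " line ", i, ": empty FASTA header"),
              class = "methclones_format_error")
      }
    } else if (!grepl(iupac, ln)) {
      bad <- regmatches(ln, regexpr("[^ACGTUMRWSYKVHDBNacgtumrwsykvhdbn]", ln))
      abort(paste0(path, " line ", i, ": non-IUPAC character '", bad,
                   "' in sequence"),
            class = "methclones_format_error")
    }
  }
  seq_lines <- setdiff(nonblank, nonblank[startsWith(lines[nonblank], ">")])
  headers <- nonblank[startsWith(lines[nonblank], ">")]
  # every header must be followed by at least one sequence line
  for (h in headers) {
    nxt <- nonblank[nonblank > h]
    if (length(nxt) == 0L || startsWith(lines[nxt[1L]], ">")) {
      abort(paste0(path, " line ", h, ": header with no sequence"),
            class = "methclones_format_error")
    }
  }
  invisible(TRUE)
}

#' Write sequences to a FASTA file
#'
#' @param records A tibble/data frame with columns `id` and `bases`, as
#'   returned by [read_fasta()].
#' @param path Output file path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(all(c("id", "bases") %in% names(records)))
  set <- Biostrings::DNAStringSet(setNames(records$bases, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read sequences embedded in a GFF3 file
#'
#' Accepts the GFF3 dialect that carries sequences in a terminal `##FASTA`
#' section. Other ways of embedding sequence in GFF are rejected with a format
#' error rather than silently returning nothing.
#'
#' @param path Path to a GFF3 file with a `##FASTA` section.
#' @return A tibble as from [read_fasta()].
#' @export
read_gff_sequences <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("GFF file not found: ", path), class = "methclones_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  mark <- which(trimws(lines) == "##FASTA")
  if (length(mark) == 0L) {
    abort(paste0(path, ": no ##FASTA section; this reader requires GFF3 with ",
                 "an embedded FASTA payload"),
          class = "methclones_format_error")
  }
  payload <- lines[seq.int(mark[1L] + 1L, length.out = length(lines) - mark[1L])]
  if (!any(startsWith(trimws(payload), ">"))) {
    abort(paste0(path, ": ##FASTA section contains no sequence records"),
          class = "methclones_format_error")
  }
  tmp <- tempfile(fileext = ".fasta")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(payload, tmp)
  out <- read_fasta(tmp)
  out$source_file <- path
  out
}

#' Read a continuous-valued measurement table
#'
#' Reads a TSV whose first row holds column ids and first column holds row
#' ids, e.g. per-clone continuous methylation scores to be binarized with
#' [binarize()].
#'
#' @param path Path to a tab-separated file.
#' @return A tibble whose first column `row_id` holds the row ids and whose
#'   remaining columns are numeric.
#' @export
read_continuous_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) {
    abort(paste0(path, ": expected row ids plus at least one value column"),
          class = "methclones_format_error")
  }
  names(df)[1L] <- "row_id"
  df$row_id <- as.character(df$row_id)
  if (anyDuplicated(df$row_id)) {
    abort(paste0(path, ": duplicate row ids"), class = "methclones_format_error")
  }
  if (anyDuplicated(names(df))) {
    abort(paste0(path, ": duplicate column ids"), class = "methclones_format_error")
  }
  for (j in seq(2L, ncol(df))) {
    if (!is.numeric(df[[j]])) {
      bad <- which(!grepl("^\\s*(NA|[-+0-9.eE]+)?\\s*$", as.character(df[[j]])))
      abort(paste0(path, ": non-numeric value in column '", names(df)[j], "'",
                   if (length(bad)) paste0(" (data row ", bad[1L], ")") else ""),
            class = "methclones_format_error")
    }
  }
  as_tibble(df)
}

#' Binarize a continuous table by thresholding
#'
#' Entries greater than or equal to `threshold` map to 1, entries below it to
#' 0. Missing values stay missing. Raising the threshold never turns a 0 into
#' a 1 (monotonicity).
#'
#' @param table A numeric matrix, or a data frame as from
#'   [read_continuous_table()] (a leading character `row_id` column is
#'   carried through untouched).
#' @param threshold Finite numeric cut point; ties (value equal to the
#'   threshold) map to 1.
#' @return An object of the same shape with 0/1 (and NA) entries.
#' @examples
#' binarize(matrix(c(0.2, 0.9), 1), threshold = 0.5)
#' @export
binarize <- function(table, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    abort("`threshold` must be a single finite number",
          class = "methclones_input_error")
  }
  if (is.matrix(table)) {
    if (!is.numeric(table)) {
      abort("non-numeric cell in continuous table",
            class = "methclones_format_error")
    }
    out <- table
    out[] <- ifelse(is.na(table), NA_real_, as.numeric(table >= threshold))
    return(out)
  }
  if (is.data.frame(table)) {
    out <- table
    cols <- names(table)
    for (nm in cols) {
      if (nm == "row_id" || (is.character(table[[nm]]) && nm == cols[1L])) next
      if (!is.numeric(table[[nm]])) {
        abort(paste0("non-numeric cell in continuous table column '", nm, "'"),
              class = "methclones_format_error")
      }
      out[[nm]] <- ifelse(is.na(table[[nm]]), NA_real_,
                          as.numeric(table[[nm]] >= threshold))
    }
    return(out)
  }
  abort("`table` must be a numeric matrix or data frame",
        class = "methclones_input_error")
}
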