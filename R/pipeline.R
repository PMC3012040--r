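pipeline_defaults <- function() {
  list(
    reference = NULL, clones = NULL, out_dir = NULL, groups = NULL,
    seed = 1L,
    match = 1, mismatch = -1, bisulfite_TC = 1, gap_open = -2, gap_extend = -1,
    max_conversion_ratio = 0.1, min_identity = 0.8, min_score = -Inf,
    cooccurrence_mode = "correlation", linkage = "complete",
    plots = TRUE, plot_format = "png", lollipop_mode = "genomic"
  )
}

#' Read a flat key=value run configuration
#'
#' One `key = value` pair per line; `#` starts a comment; values `true`,
#' `false`, numbers and bare strings are recognised. Unknown keys are
#' rejected so typos fail loudly.
#'
#' @param path Path to the config file.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path),
          class = "methclones_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  known <- names(pipeline_defaults())
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      abort(paste0("config line is not key = value: '", ln, "'"),
            class = "methclones_config_error")
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% known) {
      abort(paste0("unknown config key '", key, "'"),
            class = "methclones_config_error")
    }
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  val <- gsub('^"|"$', "", val)
  if (tolower(val) %in% c("true", "false")) return(tolower(val) == "true")
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) return(num)
  val
}

log_msg <- function(stage, msg, logfile = NULL) {
  line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

read_sequences_any <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    read_gff_sequences(path)
  } else {
    read_fasta(path)
  }
}

#' Run the full analysis pipeline
#'
#' Wires the stages end to end: read sequences, orientation-controlled
#' alignment, quality control, methylation calling, summary statistics,
#' co-occurrence, biclustering, correspondence analysis, optional two-group
#' tests, and plots. Stage outputs land under named subdirectories of
#' `out_dir`; a deterministic run manifest (package version, effective
#' config, per-stage counts, output checksums) is written last, so reruns
#' with identical inputs and seed produce identical manifests. On a stage
#' error, partial outputs are kept next to a `FAILED` marker naming the
#' stage, and the error is re-signalled (the command-line launcher maps it
#' to a non-zero exit).
#'
#' @param config A named list, or the path of a flat key=value config file
#'   (see [read_run_config()]). Required keys: `reference` (FASTA/GFF3),
#'   `clones` (FASTA/GFF3), `out_dir`. Optional: `groups` (TSV with
#'   clone_id and group columns), substitution-scheme and QC-gate
#'   parameters, `cooccurrence_mode`, `linkage`, `plots`, `plot_format`,
#'   `lollipop_mode`, `seed`.
#' @param overrides Named list overriding config values (the launcher maps
#'   command-line flags here; flags beat the file).
#' @return The manifest, invisibly, as a list.
#' @export
run_pipeline <- function(config, overrides = list()) {
  cfg <- pipeline_defaults()
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  cfg <- modifyList(cfg, config[!vapply(config, is.null, logical(1))])
  cfg <- modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])

  # resolve and check every path before any stage runs
  for (key in c("reference", "clones")) {
    if (is.null(cfg[[key]])) {
      abort(paste0("config is missing required key '", key, "'"),
            class = "methclones_config_error")
    }
    if (!file.exists(cfg[[key]])) {
      abort(paste0(key, " file not found: ", cfg[[key]]),
            class = "methclones_config_error")
    }
    cfg[[key]] <- normalizePath(cfg[[key]])
  }
  if (!is.null(cfg$groups)) {
    if (!file.exists(cfg$groups)) {
      abort(paste0("groups file not found: ", cfg$groups),
            class = "methclones_config_error")
    }
    cfg$groups <- normalizePath(cfg$groups)
  }
  if (is.null(cfg$out_dir)) {
    abort("config is missing required key 'out_dir'",
          class = "methclones_config_error")
  }
  out <- cfg$out_dir
  for (d in c("", "alignments", "qc", "calls", "stats", "plots")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }
  logfile <- file.path(out, "run.log")
  unlink(file.path(out, "FAILED"))
  stage <- "setup"
  manifest <- NULL
  tryCatch({
    set.seed(as.integer(cfg$seed))
    # provenance: echo the effective config
    echo <- cfg[order(names(cfg))]
    writeLines(paste0(names(echo), " = ",
                      vapply(echo, function(v)
                        if (is.null(v)) "" else as.character(v), character(1))),
               file.path(out, "config.echo"))
    scheme <- subst_scheme(match = cfg$match, mismatch = cfg$mismatch,
                           bisulfite_TC = cfg$bisulfite_TC,
                           gap_open = cfg$gap_open,
                           gap_extend = cfg$gap_extend)

    stage <- "read"
    ref_tbl <- read_sequences_any(cfg$reference)
    clones <- read_sequences_any(cfg$clones)
    ref <- find_cpg_sites(ref_tbl[1L, ])
    log_msg(stage, sprintf("%d clone(s), reference '%s' (%d bp, %d CpG sites)",
                           nrow(clones), ref$id, nchar(ref$bases),
                           length(ref$cpg_positions)), logfile)

    stage <- "align"
    alns <- align_clones(clones, ref$bases, scheme)
    export_alignments(alns, tsv = file.path(out, "alignments", "alignments.tsv"),
                      fasta = file.path(out, "alignments", "alignments.fasta"))
    log_msg(stage, sprintf("orientations: %s",
                           paste(names(table(alns$orientation)),
                                 table(alns$orientation),
                                 sep = "=", collapse = ", ")), logfile)

    stage <- "qc"
    qc <- qc_clones(alns, ref, scheme,
                    max_conversion_ratio = cfg$max_conversion_ratio,
                    min_identity = cfg$min_identity,
                    min_score = cfg$min_score)
    export_qc(qc, tsv = file.path(out, "qc", "qc.tsv"),
              txt = file.path(out, "qc", "qc_summary.txt"))
    log_msg(stage, sprintf("%d/%d clone(s) passed QC",
                           sum(qc$passed), nrow(qc)), logfile)

    stage <- "call"
    keep <- alns[alns$clone_id %in% qc$clone_id[qc$passed], , drop = FALSE]
    ds <- assemble_dataset(keep, ref)
    write_meth_json(ds, file.path(out, "calls", "dataset.json"))
    write_meth_matrix(ds, file.path(out, "calls", "matrix.tsv"))
    log_msg(stage, sprintf("call matrix %d x %d", nrow(ds$calls),
                           ncol(ds$calls)), logfile)

    stage <- "stats"
    summ <- methylation_summary(ds)
    write_tsv_plain(summ, file.path(out, "stats", "summary.tsv"))
    cooc <- NULL
    if (length(ds$cpg_positions) >= 2L && length(ds$clone_ids) >= 2L) {
      cooc <- cooccurrence(ds, mode = cfg$cooccurrence_mode)
      write_tsv_plain(tidy(cooc), file.path(out, "stats", "cooccurrence.tsv"))
    }
    bic <- NULL
    if (nrow(ds$calls) >= 2L && ncol(ds$calls) >= 2L) {
      bic <- tryCatch(hamming_bicluster(ds, linkage = cfg$linkage),
                      error = function(e) {
                        log_msg("stats", paste("biclustering skipped:",
                                               conditionMessage(e)), logfile)
                        NULL
                      })
      if (!is.null(bic)) {
        write_tsv_plain(tibble(clone_id = bic$row_order),
                        file.path(out, "stats", "clone_order.tsv"))
        write_tsv_plain(tibble(position = bic$col_order),
                        file.path(out, "stats", "site_order.tsv"))
      }
    }
    ca <- tryCatch(correspondence_analysis(ds),
                   error = function(e) {
                     log_msg("stats", paste("correspondence analysis skipped:",
                                            conditionMessage(e)), logfile)
                     NULL
                   })
    if (!is.null(ca)) {
      export_ca(ca, coords_tsv = file.path(out, "stats", "ca_coordinates.tsv"),
                inertia_json = file.path(out, "stats", "ca_inertia.json"))
    }
    tests <- NULL
    if (!is.null(cfg$groups)) {
      gtab <- read.delim(cfg$groups, stringsAsFactors = FALSE)
      tests <- fisher_site_test(ds, gtab, adjust = "BH")
      write_tsv_plain(tests, file.path(out, "stats", "fisher_tests.tsv"))
    }

    stage <- "plot"
    if (isTRUE(cfg$plots) && length(ds$clone_ids) > 0L) {
      ext <- paste0(".", cfg$plot_format)
      plot_lollipop(ds, summ, cooc, mode = cfg$lollipop_mode,
                    file = file.path(out, "plots", paste0("lollipop", ext)))
      if (!is.null(cooc)) {
        plot_cooccurrence_matrix(
          cooc, file = file.path(out, "plots", paste0("cooccurrence", ext)))
      }
      if (!is.null(ca)) {
        plot_ca_biplot(ca, file = file.path(out, "plots",
                                            paste0("ca_biplot", ext)))
      }
      if (!is.null(bic)) {
        plot_cluster_heatmap(ds, bic,
                             file = file.path(out, "plots",
                                              paste0("cluster_heatmap", ext)))
      }
    }

    stage <- "manifest"
    files <- sort(setdiff(list.files(out, recursive = TRUE),
                          c("run.log", "manifest.json", "config.echo")))
    sums <- tools::md5sum(file.path(out, files))
    # manifest config carries path basenames so same-seed reruns into
    # different directories yield byte-identical manifests; full paths stay
    # in config.echo
    mcfg <- echo[!vapply(echo, is.null, logical(1))]
    mcfg$out_dir <- NULL
    for (key in intersect(c("reference", "clones", "groups"), names(mcfg))) {
      mcfg[[key]] <- basename(as.character(mcfg[[key]]))
    }
    manifest <- list(
      package = "methclones",
      version = as.character(utils::packageVersion("methclones")),
      config = mcfg,
      counts = list(
        clones_in = nrow(clones),
        clones_passed_qc = sum(qc$passed),
        clones_failed_qc = sum(!qc$passed),
        matrix_rows = nrow(ds$calls),
        matrix_cols = ncol(ds$calls),
        cpg_positions = ds$cpg_positions
      ),
      ca = if (!is.null(ca)) list(
        percent_inertia = ca$percent_inertia,
        total_inertia = ca$total_inertia
      ),
      outputs = setNames(as.list(unname(sums)), files)
    )
    jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    log_msg("done", paste("manifest written to",
                          file.path(out, "manifest.json")), logfile)
  }, error = function(e) {
    writeLines(paste0("stage: ", stage, "\n", conditionMessage(e)),
               file.path(out, "FAILED"))
    log_msg(stage, paste("FAILED:", conditionMessage(e)), logfile)
    abort(paste0("pipeline failed at stage '", stage, "': ",
                 conditionMessage(e)),
          class = "methclones_pipeline_error", parent = e)
  })
  invisible(manifest)
}
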