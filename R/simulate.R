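#' Configuration for a simulated bisulfite experiment
#'
#' Describes a synthetic reference and set of bisulfite clones with fully
#' known ground truth, so every pipeline contract (orientation recovery,
#' conversion-ratio estimation, methylation-call correctness) can be tested
#' without external data.
#'
#' @param ref_length Reference length in bp.
#' @param cpg_positions 1-based positions of the C of each planted CpG; must
#'   be at least 2 apart (an overlapping CG placement is rejected) and fit
#'   within the reference.
#' @param n_clones Number of clones (ignored when `methylation_pattern` is a
#'   matrix).
#' @param methylation_pattern Either a clone-by-CpG 0/1 matrix of true
#'   methylation states, or a vector of per-site methylation probabilities
#'   (recycled across sites) from which patterns are drawn.
#' @param n_noncpg_c Number of non-CpG cytosines planted in the reference
#'   (the denominators of the conversion ratio).
#' @param conversion_failure_p Probability that an unmethylated C escapes
#'   bisulfite conversion (stays C) in a clone.
#' @param seq_error_p Per-base substitution error probability.
#' @param orientations Per-clone orientation transforms applied to the
#'   finished clone (recycled): `"identity"`, `"reverse"`, `"complement"`,
#'   `"reverse_complement"`.
#' @param spans Optional tibble `clone_id`-free coverage windows: columns
#'   `start`, `end` (1-based, recycled) restricting each clone to a
#'   sub-region of the reference; default full length.
#' @param clean_calls If TRUE (default) substitution errors are never
#'   planted at CpG cytosine positions, so call-correctness tests are
#'   isolated from error handling.
#' @param seed Integer seed; the whole simulation is one seeded random
#'   stream, and equal seeds give byte-identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(ref_length = 100L,
                       cpg_positions = c(7L, 32L, 48L, 55L, 73L),
                       n_clones = 4L,
                       methylation_pattern = 0.5,
                       n_noncpg_c = 10L,
                       conversion_failure_p = 0,
                       seq_error_p = 0,
                       orientations = "identity",
                       spans = NULL,
                       clean_calls = TRUE,
                       seed = 1L) {
  cpg_positions <- as.integer(sort(cpg_positions))
  if (length(cpg_positions)) {
    if (any(cpg_positions < 1L) || any(cpg_positions + 1L > ref_length)) {
      abort("CpG positions must satisfy 1 <= p and p + 1 <= ref_length",
            class = "methclones_input_error")
    }
    if (any(diff(cpg_positions) < 2L)) {
      abort("CpG positions overlap: adjacent positions p, p+1 cannot both hold a CG",
            class = "methclones_input_error")
    }
  }
  if (is.matrix(methylation_pattern)) {
    if (ncol(methylation_pattern) != length(cpg_positions)) {
      abort("methylation_pattern columns must match cpg_positions",
            class = "methclones_input_error")
    }
    if (!all(methylation_pattern %in% c(0, 1))) {
      abort("methylation_pattern must be 0/1", class = "methclones_input_error")
    }
    n_clones <- nrow(methylation_pattern)
  }
  stopifnot(conversion_failure_p >= 0, conversion_failure_p <= 1,
            seq_error_p >= 0, seq_error_p <= 1)
  orientations <- match.arg(orientations,
                            c("identity", "reverse", "complement",
                              "reverse_complement"),
                            several.ok = TRUE)
  structure(
    list(ref_length = as.integer(ref_length), cpg_positions = cpg_positions,
         n_clones = as.integer(n_clones),
         methylation_pattern = methylation_pattern,
         n_noncpg_c = as.integer(n_noncpg_c),
         conversion_failure_p = conversion_failure_p,
         seq_error_p = seq_error_p, orientations = orientations,
         spans = spans, clean_calls = clean_calls, seed = as.integer(seed)),
    class = "sim_config"
  )
}

# run code under a seeded RNG without disturbing the caller's stream
with_sim_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a reference sequence with planted CpG and non-CpG cytosines
#'
#' The background is drawn from A/G/T so that the only cytosines are the
#' planted ones: CG dinucleotides exactly at `cfg$cpg_positions` plus
#' `cfg$n_noncpg_c` non-CpG Cs (never followed by G). By construction a CpG
#' scan of the result returns exactly the requested positions.
#'
#' @param cfg A [sim_config()].
#' @return A list: `record` (single-row sequence tibble), `ref`
#'   (`reference_sequence`), `noncpg_c_positions`.
#' @export
simulate_reference <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed, {
    len <- cfg$ref_length
    cpg <- cfg$cpg_positions
    bases <- sample(c("A", "G", "T"), len, replace = TRUE)
    bases[cpg] <- "C"
    bases[cpg + 1L] <- "G"
    candidates <- setdiff(seq_len(len), c(cpg, cpg + 1L))
    if (length(candidates) < cfg$n_noncpg_c) {
      abort("reference too short for the requested non-CpG C count",
            class = "methclones_input_error")
    }
    noncpg <- sort(sample(candidates, cfg$n_noncpg_c))
    bases[noncpg] <- "C"
    # a planted C must not create a CG: fix any following G (positions in a
    # CpG footprint were never candidates, so this never breaks a CpG)
    for (q in noncpg) {
      if (q < len && bases[q + 1L] == "G") {
        bases[q + 1L] <- sample(c("A", "T"), 1L)
      }
    }
    seqs <- paste(bases, collapse = "")
    ref <- find_cpg_sites(seqs, id = "sim_ref")
    if (!identical(ref$cpg_positions, cpg)) {
      abort("internal error: simulated reference CpG scan mismatch")
    }
    list(record = tibble(id = "sim_ref", bases = seqs,
                         source_file = NA_character_),
         ref = ref,
         noncpg_c_positions = noncpg)
  })
}

apply_orientation <- function(bases, orientation) {
  d <- Biostrings::DNAString(bases)
  as.character(switch(orientation,
    identity = d,
    reverse = Biostrings::reverse(d),
    complement = Biostrings::complement(d),
    reverse_complement = Biostrings::reverseComplement(d)
  ))
}

#' Simulate bisulfite clone sequences with known ground truth
#'
#' Each clone is copied from the reference (optionally restricted to a
#' coverage window), bisulfite-converted according to its true methylation
#' pattern (methylated CpG Cs stay C, everything else C becomes T except
#' with probability `conversion_failure_p`), perturbed by substitution
#' errors at rate `seq_error_p`, and finally transformed to its configured
#' orientation. All random draws are recorded in the ground-truth object.
#'
#' @param ref_sim Result of [simulate_reference()].
#' @param cfg The same [sim_config()].
#' @return A list: `clones` (sequence tibble), `truth` (list with the
#'   pattern matrix and a per-clone tibble of orientation, span, planted
#'   conversion failures and substitution errors).
#' @export
simulate_clones <- function(ref_sim, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_sim_seed(cfg$seed + 1L, {
    n <- cfg$n_clones
    k <- length(cfg$cpg_positions)
    pattern <- if (is.matrix(cfg$methylation_pattern)) {
      cfg$methylation_pattern
    } else {
      matrix(as.numeric(stats::runif(n * k) <
                          rep(cfg$methylation_pattern, length.out = k)[
                            rep(seq_len(k), each = n)]),
             n, k)
    }
    rownames(pattern) <- paste0("clone", seq_len(n))
    len <- cfg$ref_length
    spans <- cfg$spans
    ori <- rep(cfg$orientations, length.out = n)
    refchars <- strsplit(ref_sim$record$bases, "", fixed = TRUE)[[1L]]
    per_clone <- vector("list", n)
    seqs <- character(n)
    for (i in seq_len(n)) {
      span <- if (is.null(spans)) c(1L, len) else
        c(as.integer(spans$start[(i - 1L) %% nrow(spans) + 1L]),
          as.integer(spans$end[(i - 1L) %% nrow(spans) + 1L]))
      chars <- refchars
      # bisulfite chemistry on the clone strand
      meth_cpg <- cfg$cpg_positions[pattern[i, ] == 1]
      unmeth_cpg <- setdiff(cfg$cpg_positions, meth_cpg)
      chars[unmeth_cpg] <- "T"
      fail_at <- integer(0)
      for (q in ref_sim$noncpg_c_positions) {
        if (stats::runif(1L) < cfg$conversion_failure_p) {
          fail_at <- c(fail_at, q)          # escaped conversion, stays C
        } else {
          chars[q] <- "T"
        }
      }
      # sequencing substitution errors
      err_at <- integer(0)
      if (cfg$seq_error_p > 0) {
        eligible <- seq_len(len)
        if (cfg$clean_calls) eligible <- setdiff(eligible, cfg$cpg_positions)
        hit <- eligible[stats::runif(length(eligible)) < cfg$seq_error_p]
        for (q in hit) {
          chars[q] <- sample(setdiff(c("A", "C", "G", "T"), chars[q]), 1L)
        }
        err_at <- hit
      }
      fwd <- paste(chars[span[1L]:span[2L]], collapse = "")
      seqs[i] <- apply_orientation(fwd, ori[i])
      per_clone[[i]] <- tibble(
        clone_id = rownames(pattern)[i],
        orientation = ori[i],
        span_start = span[1L], span_end = span[2L],
        n_conversion_failures = length(intersect(fail_at, span[1L]:span[2L])),
        conversion_failure_positions = list(intersect(fail_at, span[1L]:span[2L])),
        error_positions = list(intersect(err_at, span[1L]:span[2L]))
      )
    }
    list(
      clones = tibble(id = rownames(pattern), bases = seqs,
                      source_file = NA_character_),
      truth = list(pattern = pattern,
                   clones = dplyr::bind_rows(per_clone),
                   noncpg_c_positions = ref_sim$noncpg_c_positions,
                   config = cfg)
    )
  })
}

#' Simulate a full experiment (reference plus clones)
#'
#' @param cfg A [sim_config()].
#' @return A list with `reference` (sequence tibble), `ref`
#'   (`reference_sequence`), `clones` (sequence tibble), `truth`.
#' @export
simulate_experiment <- function(cfg) {
  rs <- simulate_reference(cfg)
  cl <- simulate_clones(rs, cfg)
  list(reference = rs$record, ref = rs$ref,
       noncpg_c_positions = rs$noncpg_c_positions,
       clones = cl$clones, truth = cl$truth)
}

#' Write a simulated experiment to disk
#'
#' Produces `reference.fasta`, `clones.fasta` and `ground_truth.json` under
#' `dir`. Output is byte-identical for equal configs (reproducibility
#' contract).
#'
#' @param sim Result of [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(sim$reference, file.path(dir, "reference.fasta"))
  write_fasta(sim$clones, file.path(dir, "clones.fasta"))
  truth <- sim$truth
  obj <- list(
    schema = "methclones/ground_truth/1",
    pattern = unname(apply(truth$pattern, 1L, as.list, simplify = FALSE)),
    clone_ids = rownames(truth$pattern),
    cpg_positions = truth$config$cpg_positions,
    noncpg_c_positions = truth$noncpg_c_positions,
    clones = truth$clones[setdiff(names(truth$clones),
                                  c("conversion_failure_positions",
                                    "error_positions"))],
    conversion_failure_positions = truth$clones$conversion_failure_positions,
    error_positions = truth$clones$error_positions
  )
  jsonlite::write_json(obj, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
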