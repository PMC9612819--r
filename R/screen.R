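CATEGORY_ORDER <- c("snv", "expression", "deletion", "fusion", "ig_rearrangement")

.resolve_target_paths <- function(targets) {
  if (is.character(targets) && length(targets) == 1L && dir.exists(targets)) {
    files <- list.files(targets, pattern = "\\.(fa|fasta)$", full.names = TRUE)
    cats <- sub("\\.(fa|fasta)$", "", basename(files))
    files <- files[cats %in% TARGET_CATEGORIES]
    cats <- cats[cats %in% TARGET_CATEGORIES]
    if (!length(files)) stop("no per-category target FASTAs in ", targets)
    stats::setNames(as.list(files), cats)
  } else if (is.list(targets)) {
    bad <- setdiff(names(targets), TARGET_CATEGORIES)
    if (length(bad)) stop("unknown target categories: ", paste(bad, collapse = ", "))
    targets
  } else {
    stop("targets must be a directory of <category>.fa files or a named list")
  }
}

#' Run the full targeted screen on a sample
#'
#' Wires the whole pipeline: index the reads into a k-mer count table,
#' evaluate each target category (snv by path assembly; expression, deletion,
#' fusion and IG rearrangement by exact presence), apply the reporting
#' filters, and compile the single per-sample report. Categories are
#' evaluated in a fixed order (snv, expression, deletion, fusion,
#' ig_rearrangement); order affects only the log.
#'
#' @param fastqs character vector of one or two FASTQ(.gz) paths, or a
#'   character vector of raw read sequences (`reads_are_sequences = TRUE`).
#' @param targets directory containing `<category>.fa` files, or a named
#'   list mapping categories to FASTA paths (or directly to `target_set`s).
#' @param k word length (default 31). Must match `table` when one is reused.
#' @param canonical strand-collapsing policy for counting (default TRUE).
#' @param min_count graph admission threshold (default 1; reporting
#'   thresholds live in `policy`).
#' @param policy a [filter_policy()].
#' @param population_af optional population-variant data.frame (see
#'   [call_variants()]).
#' @param sample_id sample label (default derived from the first FASTQ).
#' @param out_dir optional output directory: writes `report.tsv`, one
#'   `<category>_calls.tsv` per evaluated category, and `screen.log`.
#' @param table optional pre-built `kmer_count_table` to reuse; its k and
#'   policy must match `k`/`canonical`.
#' @param reads_are_sequences treat `fastqs` as raw sequences (used by the
#'   simulator round-trip).
#' @return list with `report` (data.frame), `calls` (per-category
#'   data.frames), `table`, and `log` (character vector).
#' @export
run_screen <- function(fastqs, targets, k = 31L, canonical = TRUE,
                       min_count = 1L, policy = filter_policy(),
                       population_af = NULL, sample_id = NULL,
                       out_dir = NULL, table = NULL,
                       reads_are_sequences = FALSE) {
  log <- character(0)
  note <- function(...) {
    log <<- c(log, paste0(...))
  }
  if (is.null(sample_id)) {
    sample_id <- if (reads_are_sequences || !length(fastqs)) "sample" else {
      sub("(_R?1)?\\.(fastq|fq)(\\.gz)?$", "", basename(fastqs[1]))
    }
  }
  if (is.null(table)) {
    reads <- if (reads_are_sequences) fastqs else {
      if (length(fastqs)) read_fastq_reads(fastqs) else character(0)
    }
    table <- count_kmers(reads, k = k, canonical = canonical)
    note("indexed ", length(reads), " reads into ",
         length(ls(table$counts)), " distinct ", k, "-mers")
  } else {
    if (table$k != k) {
      stop("reused count table has k = ", table$k,
           " but the run is configured with k = ", k)
    }
    if (table$canonical != canonical) {
      stop("reused count table canonicalization policy does not match the run")
    }
    note("reusing count table with ", length(ls(table$counts)),
         " distinct ", k, "-mers")
  }

  tpaths <- .resolve_target_paths(targets)
  sets <- list()
  for (cat in intersect(CATEGORY_ORDER, names(tpaths))) {
    t <- tpaths[[cat]]
    sets[[cat]] <- if (inherits(t, "target_set")) t else {
      read_target_fasta(t, cat, k = k)
    }
  }

  calls <- list()
  report_parts <- list()
  for (cat in names(sets)) {
    set <- sets[[cat]]
    if (cat == "snv") {
      pcs <- list()
      for (rec in set$records) {
        pcs <- c(pcs, walk_paths(table, rec, min_count = min_count))
      }
      calls[[cat]] <- path_calls_df(pcs)
      rows <- call_variants(pcs, targets = set, policy = policy,
                            population_af = population_af,
                            sample_id = sample_id)
    } else {
      pres <- presence_results(table, set, min_count = min_count)
      calls[[cat]] <- pres
      rows <- switch(cat,
        expression = call_dux4(pres, policy = policy, sample_id = sample_id),
        deletion = call_deletions(pres, policy = policy, sample_id = sample_id),
        call_fusions(pres, policy = policy, sample_id = sample_id))
    }
    note(cat, ": ", length(set$records), " targets evaluated, ",
         nrow(rows), " calls retained")
    report_parts[[cat]] <- rows
  }
  report <- do.call(compile_report,
                    c(list(sample_id), unname(report_parts),
                      list(policy = policy, k = k)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    compile_report(sample_id, report,
                   policy = policy, k = k,
                   path = file.path(out_dir, "report.tsv"))
    for (cat in names(calls)) {
      utils::write.table(calls[[cat]],
                         file.path(out_dir, paste0(cat, "_calls.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    writeLines(log, file.path(out_dir, "screen.log"))
  }
  list(report = report, calls = calls, table = table, log = log)
}
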