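#' Reporting filter policy
#'
#' The numeric thresholds governing which raw detections are retained in the
#' final report and which are flagged low-confidence. Defaults encode the
#' published screening thresholds; every exclusion is phrased "less than", so
#' all thresholds are boundary-inclusive on the keep side (e.g. a deletion
#' junction at minimum coverage exactly 10 is kept).
#'
#' @param dux4_min_targets minimum number of qualifying expression windows
#'   for an expression-marker call (default 4).
#' @param dux4_min_cov minimum per-window coverage for a window to qualify
#'   (default 10).
#' @param deletion_min_cov minimum junction coverage for an
#'   intragenic-deletion row (default 10).
#' @param variant_min_support minimum variant-path coverage for a
#'   sequence-variant row (default 5); valid as a read-support proxy when
#'   reads span the whole target, which 62-72b targets guarantee for >=75b
#'   reads.
#' @param fusion_low_conf_cov fusion/IG rows below this minimum coverage are
#'   flagged low-confidence (default 5).
#' @param snp_af_threshold allele-frequency threshold used when building
#'   alternate targets (default 0.01).
#' @param benign_af_threshold population allele frequency above which a
#'   matching variant is flagged as a likely benign polymorphism
#'   (default 0.01).
#' @param homopolymer_flag_len insertions/deletions extending a homopolymer
#'   run of at least this length are flagged as possible sequencing
#'   artifacts (default 5).
#' @return an object of class `filter_policy`.
#' @export
filter_policy <- function(dux4_min_targets = 4L,
                          dux4_min_cov = 10L,
                          deletion_min_cov = 10L,
                          variant_min_support = 5L,
                          fusion_low_conf_cov = 5L,
                          snp_af_threshold = 0.01,
                          benign_af_threshold = 0.01,
                          homopolymer_flag_len = 5L) {
  pol <- list(dux4_min_targets = as.integer(dux4_min_targets),
              dux4_min_cov = as.integer(dux4_min_cov),
              deletion_min_cov = as.integer(deletion_min_cov),
              variant_min_support = as.integer(variant_min_support),
              fusion_low_conf_cov = as.integer(fusion_low_conf_cov),
              snp_af_threshold = snp_af_threshold,
              benign_af_threshold = benign_af_threshold,
              homopolymer_flag_len = as.integer(homopolymer_flag_len))
  ints <- pol[c("dux4_min_targets", "dux4_min_cov", "deletion_min_cov",
                "variant_min_support", "fusion_low_conf_cov",
                "homopolymer_flag_len")]
  stopifnot(all(unlist(ints) >= 1L),
            pol$snp_af_threshold >= 0, pol$snp_af_threshold <= 1,
            pol$benign_af_threshold >= 0, pol$benign_af_threshold <= 1)
  structure(pol, class = "filter_policy")
}

.report_row <- function(sample_id = "", alteration_class, target_id, genes,
                        nucleotide_change = "", protein_change = "",
                        min_coverage, ratio = NA_real_, flags = character(0)) {
  data.frame(
    sample_id = sample_id,
    alteration_class = alteration_class,
    target_id = target_id,
    genes = paste(genes, collapse = ","),
    nucleotide_change = nucleotide_change,
    protein_change = protein_change,
    min_coverage = as.integer(min_coverage),
    ratio = ratio,
    confidence = if (length(flags)) "low" else "high",
    flags = paste(flags, collapse = ","),
    stringsAsFactors = FALSE
  )
}

.empty_report <- function() {
  data.frame(sample_id = character(0), alteration_class = character(0),
             target_id = character(0), genes = character(0),
             nucleotide_change = character(0), protein_change = character(0),
             min_coverage = integer(0), ratio = numeric(0),
             confidence = character(0), flags = character(0),
             stringsAsFactors = FALSE)
}

#' Presence results for a target set
#'
#' Convenience wrapper running [detect_presence()] over every record of a
#' set, as required by the fusion, IG-rearrangement and expression callers.
#'
#' @param table a `kmer_count_table`.
#' @param set a `target_set`.
#' @param min_count graph admission threshold (default 1).
#' @return data.frame: target_id, category, genes, min_cov, present.
#' @export
presence_results <- function(table, set, min_count = 1L) {
  if (!length(set$records)) {
    return(data.frame(target_id = character(0), category = character(0),
                      genes = character(0), min_cov = integer(0),
                      present = logical(0), stringsAsFactors = FALSE))
  }
  rows <- lapply(set$records, function(rec) {
    pr <- detect_presence(table, rec, min_count = min_count)
    data.frame(target_id = rec$id, category = rec$category,
               genes = paste(rec$genes, collapse = ","),
               min_cov = pr$min_cov, present = pr$present,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Report fusion and IG-rearrangement detections
#'
#' One row per present target (exact-match rule: every window of the target
#' observed). Rows whose minimum coverage falls below
#' `policy$fusion_low_conf_cov` are retained but flagged low-confidence, the
#' regime in which read-through or cis-splicing chimeras are known to mimic
#' true fusions. Reciprocal fusion targets yield separate rows.
#'
#' @param presence data.frame from [presence_results()] for fusion and/or
#'   ig_rearrangement sets.
#' @param policy a `filter_policy`.
#' @param sample_id sample label.
#' @return data.frame of report rows.
#' @export
call_fusions <- function(presence, policy = filter_policy(), sample_id = "") {
  keep <- presence[presence$present, , drop = FALSE]
  if (!nrow(keep)) return(.empty_report())
  rows <- lapply(seq_len(nrow(keep)), function(i) {
    flags <- character(0)
    if (keep$min_cov[i] < policy$fusion_low_conf_cov) {
      flags <- "low_kmer_coverage"
    }
    cls <- if (keep$category[i] == "ig_rearrangement") "ig_rearrangement" else "fusion"
    .report_row(sample_id, cls, keep$target_id[i],
                keep$genes[i], min_coverage = keep$min_cov[i], flags = flags)
  })
  do.call(rbind, rows)
}

#' Call an expression marker from tiled windows
#'
#' Emits one expression-marker row if and only if at least
#' `policy$dux4_min_targets` windows reach a minimum coverage of
#' `policy$dux4_min_cov` — the filter that separates genuinely expressing
#' samples (many windows at high coverage) from spurious assembly of one or
#' two windows at minimal coverage. The row carries the count of qualifying
#' windows and their mean minimum coverage.
#'
#' @param presence data.frame from [presence_results()] for the full
#'   expression target set.
#' @param policy a `filter_policy`.
#' @param sample_id sample label.
#' @param marker marker gene label for the row (default taken from the
#'   targets' genes field).
#' @return data.frame with zero rows or one row.
#' @export
call_dux4 <- function(presence, policy = filter_policy(), sample_id = "",
                      marker = NULL) {
  qual <- presence[presence$present & presence$min_cov >= policy$dux4_min_cov, ,
                   drop = FALSE]
  if (nrow(qual) < policy$dux4_min_targets) return(.empty_report())
  if (is.null(marker)) {
    g <- unique(qual$genes[nzchar(qual$genes)])
    marker <- if (length(g)) g[1] else "expression_marker"
  }
  row <- .report_row(
    sample_id, "expression_marker",
    target_id = sprintf("%s_expression", marker),
    genes = marker,
    min_coverage = min(qual$min_cov))
  row$nucleotide_change <- sprintf("%d/%d windows detected; mean min coverage %.1f",
                                   nrow(qual), nrow(presence),
                                   mean(qual$min_cov))
  row
}

#' Report intragenic-deletion isoforms
#'
#' One row per present deletion-junction target with minimum coverage at or
#' above `policy$deletion_min_cov`; junctions assembled below the threshold
#' likely represent low numbers of aberrantly spliced transcripts rather
#' than true deletions and are only retained in the verbose log.
#'
#' @param presence data.frame from [presence_results()] for the deletion
#'   set.
#' @param policy a `filter_policy`.
#' @param sample_id sample label.
#' @param verbose_log optional path; below-threshold detections are appended
#'   there.
#' @return data.frame of report rows.
#' @export
call_deletions <- function(presence, policy = filter_policy(),
                           sample_id = "", verbose_log = NULL) {
  det <- presence[presence$present, , drop = FALSE]
  keep <- det[det$min_cov >= policy$deletion_min_cov, , drop = FALSE]
  dropped <- det[det$min_cov < policy$deletion_min_cov, , drop = FALSE]
  if (!is.null(verbose_log) && nrow(dropped)) {
    cat(sprintf("deletion junction %s detected below threshold (min_cov=%d)\n",
                dropped$target_id, dropped$min_cov),
        file = verbose_log, append = TRUE, sep = "")
  }
  if (!nrow(keep)) return(.empty_report())
  do.call(rbind, lapply(seq_len(nrow(keep)), function(i) {
    .report_row(sample_id, "intragenic_deletion", keep$target_id[i],
                keep$genes[i], min_coverage = keep$min_cov[i])
  }))
}

# does an inserted/deleted allele extend a homopolymer run of >= run_len in
# the target context around the variant position?
.extends_homopolymer <- function(target_seq, pos, allele, run_len) {
  if (!nchar(allele)) return(FALSE)
  b <- unique(strsplit(allele, "", fixed = TRUE)[[1]])
  if (length(b) != 1L) return(FALSE)
  n <- nchar(target_seq)
  # scan outward from the variant locus for a run of base b
  left <- pos
  while (left > 0L && substr(target_seq, left, left) == b) left <- left - 1L
  right <- pos + 1L
  while (right <= n && substr(target_seq, right, right) == b) right <- right + 1L
  (right - left - 1L) >= run_len
}

#' Report sequence variants from assembled paths
#'
#' One row per non-Reference, non-Absent path call with variant-path minimum
#' coverage at or above `policy$variant_min_support` (operationalizing the
#' requirement of 5 reads spanning the target region carrying the altered
#' allele). Rows matching a supplied population variant above the benign
#' frequency threshold are flagged `likely_benign_polymorphism`; insertions
#' and deletions whose allele extends a homopolymer run are flagged
#' `possible_homopolymer_artifact`, the mechanism behind recurrent false
#' positive indel calls in homopolymer stretches.
#'
#' @param calls list of `path_call`s for the snv target set (or one call).
#' @param targets the `target_set` the calls were made against (for protein
#'   annotation and homopolymer context); optional.
#' @param policy a `filter_policy`.
#' @param population_af optional data.frame (`chrom`,`pos`,`ref`,`alt`,`af`)
#'   or a named numeric vector keyed `"<target_id>:<pos><ref>><alt>"` of
#'   population allele frequencies.
#' @param sample_id sample label.
#' @return data.frame of report rows.
#' @export
call_variants <- function(calls, targets = NULL, policy = filter_policy(),
                          population_af = NULL, sample_id = "") {
  if (inherits(calls, "path_call")) calls <- list(calls)
  rec_by_id <- list()
  if (!is.null(targets)) {
    for (r in targets$records) rec_by_id[[r$id]] <- r
  }
  rows <- list()
  for (p in calls) {
    if (p$path_type %in% c("Reference", "Absent")) next
    if (p$min_coverage < policy$variant_min_support) next
    rec <- rec_by_id[[p$target_id]]
    flags <- character(0)
    v <- p$variants
    nchange <- path_calls_df(list(p))$variants
    pchange <- ""
    if (!is.null(rec) && rec$category == "snv" && !is.null(rec$frame_offset)) {
      pc <- suppressMessages(annotate_protein(p, rec))
      if (!is.na(pc)) pchange <- pc
    }
    if (nrow(v) == 1L && nchar(v$ref[1]) != nchar(v$alt[1]) && !is.null(rec)) {
      indel_allele <- if (nchar(v$alt[1]) > nchar(v$ref[1])) v$alt[1] else v$ref[1]
      if (.extends_homopolymer(rec$sequence, v$pos[1], indel_allele,
                               policy$homopolymer_flag_len)) {
        flags <- c(flags, "possible_homopolymer_artifact")
      }
    }
    if (!is.null(population_af) && nrow(v) == 1L) {
      af <- NA_real_
      if (is.data.frame(population_af)) {
        if (!is.null(rec) && !is.null(rec$coord_map) &&
            v$pos[1] + 1L <= nrow(rec$coord_map)) {
          gp <- rec$coord_map[v$pos[1] + 1L, ]
          hit <- population_af[population_af$chrom == gp$chrom &
                                 population_af$pos == gp$pos, , drop = FALSE]
          if (nrow(hit)) af <- max(hit$af)
        }
      } else {
        key <- sprintf("%s:%d%s>%s", p$target_id, v$pos[1], v$ref[1], v$alt[1])
        if (key %in% names(population_af)) af <- population_af[[key]]
      }
      if (!is.na(af) && af > policy$benign_af_threshold) {
        flags <- c(flags, "likely_benign_polymorphism")
      }
    }
    genes <- if (!is.null(rec)) rec$genes else character(0)
    rows[[length(rows) + 1L]] <- .report_row(
      sample_id, "sequence_variant", p$target_id, genes,
      nucleotide_change = nchange, protein_change = pchange,
      min_coverage = p$min_coverage, ratio = p$ratio, flags = flags)
  }
  if (!length(rows)) return(.empty_report())
  do.call(rbind, rows)
}

#' Compile the single per-sample report
#'
#' Merges the per-class rows, orders them deterministically (class, then
#' gene, then target id) and writes a TSV whose commented header carries the
#' tool version, the policy values and k, so a report is self-describing.
#'
#' @param sample_id sample label written into every row.
#' @param ... data.frames of report rows (any of them may be empty).
#' @param policy the `filter_policy` used (recorded in the header).
#' @param k word length used (recorded in the header).
#' @param path output TSV path; `NULL` returns the assembled data.frame
#'   without writing.
#' @return the assembled report data.frame, invisibly when written.
#' @export
compile_report <- function(sample_id, ..., policy = filter_policy(),
                           k = 31L, path = NULL) {
  parts <- Filter(function(x) is.data.frame(x) && nrow(x) > 0, list(...))
  report <- if (length(parts)) do.call(rbind, parts) else .empty_report()
  if (nrow(report)) {
    report$sample_id <- sample_id
    ord <- order(report$alteration_class, report$genes, report$target_id,
                 method = "radix")
    report <- report[ord, , drop = FALSE]
    rownames(report) <- NULL
  }
  if (is.null(path)) return(report)
  con <- file(path, "w")
  on.exit(close(con))
  ver <- tryCatch(as.character(utils::packageVersion("kmerscreen")),
                  error = function(e) "dev")
  writeLines(c(
    paste0("# kmerscreen v", ver, " variant report"),
    paste0("# sample=", sample_id),
    paste0("# k=", k),
    paste0("# policy: ",
           paste(names(unclass(policy)), unlist(unclass(policy)),
                 sep = "=", collapse = " "))
  ), con)
  utils::write.table(report, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(report)
}
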