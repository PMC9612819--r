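TARGET_CATEGORIES <- c("fusion", "ig_rearrangement", "expression", "snv", "deletion")

#' Construct a target record
#'
#' A target record is one short curated sequence representing a known
#' alteration: a fusion junction, the in-frame neighbourhood of a coding
#' variant, an intragenic-deletion exon-exon junction, an expression-marker
#' window, or an immunoglobulin-rearrangement breakpoint candidate.
#'
#' Coordinates stored on a record are 0-based half-open; conversion from the
#' 1-based inclusive GTF convention happens only at annotation import.
#'
#' @param id unique target identifier.
#' @param category one of `"fusion"`, `"ig_rearrangement"`, `"expression"`,
#'   `"snv"`, `"deletion"`.
#' @param sequence uppercase ACGT string.
#' @param genes character vector of gene symbols involved.
#' @param transcript_ids character vector of transcript identifiers.
#' @param breakpoint_offset for fusion/deletion targets: 0-based position of
#'   the first base after the junction.
#' @param codon_span for snv targets: integer pair of amino-acid positions
#'   (first, last) covered by the targeted codons.
#' @param frame_offset for snv targets: in-target offset (0, 1 or 2) of the
#'   first complete codon.
#' @param codon_offset for snv targets: 0-based in-target offset of the first
#'   base of the codon at `codon_span[1]` (33 for builder-made targets, which
#'   carry 33-base flanks).
#' @param notes free-text provenance.
#' @param chrom,coord_map optional construction metadata: chromosome name and
#'   an integer vector giving, per target base, the 1-based genomic position
#'   it was extracted from (NA where not applicable). Used to map population
#'   variants into the target; not serialized to FASTA.
#' @return an object of class `target_record`.
#' @export
target_record <- function(id, category, sequence,
                          genes = character(0),
                          transcript_ids = character(0),
                          breakpoint_offset = NULL,
                          codon_span = NULL,
                          frame_offset = NULL,
                          codon_offset = NULL,
                          notes = "",
                          chrom = NULL,
                          coord_map = NULL) {
  rec <- structure(
    list(id = as.character(id),
         category = match.arg(category, TARGET_CATEGORIES),
         sequence = toupper(as.character(sequence)),
         genes = as.character(genes),
         transcript_ids = as.character(transcript_ids),
         breakpoint_offset = if (!is.null(breakpoint_offset)) as.integer(breakpoint_offset),
         codon_span = if (!is.null(codon_span)) as.integer(codon_span),
         frame_offset = if (!is.null(frame_offset)) as.integer(frame_offset),
         codon_offset = if (!is.null(codon_offset)) as.integer(codon_offset),
         notes = as.character(notes),
         chrom = chrom,
         coord_map = coord_map),
    class = "target_record"
  )
  rec
}

#' Validate a target record
#'
#' Checks the structural invariants: ACGT-only sequence of length >= k,
#' a junction offset strictly inside fusion/deletion targets, and an in-frame
#' codon span fully contained in snv targets.
#'
#' @param rec a `target_record`.
#' @param k minimum usable sequence length (the screening word length).
#' @return invisibly `TRUE`; otherwise a character vector of problems is
#'   attached to the error thrown.
#' @export
validate_target_record <- function(rec, k = 31L) {
  probs <- character(0)
  if (!nzchar(rec$id)) probs <- c(probs, "empty id")
  if (grepl("[^ACGT]", rec$sequence)) {
    probs <- c(probs, sprintf("record '%s': sequence contains non-ACGT symbols", rec$id))
  }
  n <- nchar(rec$sequence)
  if (n < k) {
    probs <- c(probs, sprintf("record '%s': sequence length %d < k = %d", rec$id, n, k))
  }
  if (rec$category %in% c("fusion", "deletion")) {
    bo <- rec$breakpoint_offset
    if (is.null(bo) || length(bo) != 1L || is.na(bo) || bo <= 0L || bo >= n) {
      probs <- c(probs, sprintf(
        "record '%s': %s target needs breakpoint_offset strictly inside the sequence",
        rec$id, rec$category))
    }
  }
  if (rec$category == "snv") {
    cs <- rec$codon_span; fo <- rec$frame_offset
    if (is.null(cs) || length(cs) != 2L || any(is.na(cs)) || cs[1] > cs[2]) {
      probs <- c(probs, sprintf("record '%s': snv target needs codon_span (start <= end)", rec$id))
    }
    if (is.null(fo) || length(fo) != 1L || is.na(fo) || !fo %in% 0:2) {
      probs <- c(probs, sprintf("record '%s': snv target needs frame_offset in {0,1,2}", rec$id))
    }
    if (!length(probs) && !is.null(rec$codon_offset)) {
      ncod <- cs[2] - cs[1] + 1L
      if (rec$codon_offset + 3L * ncod > n) {
        probs <- c(probs, sprintf("record '%s': targeted codons not fully contained", rec$id))
      }
    }
  }
  if (length(probs)) stop(paste(probs, collapse = "; "))
  invisible(TRUE)
}

#' Construct a target set
#'
#' A category-homogeneous collection of target records with unique ids.
#'
#' @param category category shared by all records.
#' @param records list of `target_record`s.
#' @param k word length used for validation (default 31).
#' @param validate validate each record (default `TRUE`).
#' @return an object of class `target_set`.
#' @export
target_set <- function(category, records, k = 31L, validate = TRUE) {
  category <- match.arg(category, TARGET_CATEGORIES)
  stopifnot(is.list(records))
  ids <- vapply(records, function(r) r$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate target ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  bad_cat <- vapply(records, function(r) r$category != category, logical(1))
  if (any(bad_cat)) {
    stop("records with mismatched category: ", paste(ids[bad_cat], collapse = ", "))
  }
  if (validate) {
    errs <- character(0)
    for (r in records) {
      e <- tryCatch({ validate_target_record(r, k = k); NULL },
                    error = function(e) conditionMessage(e))
      if (!is.null(e)) errs <- c(errs, e)
    }
    if (length(errs)) {
      stop("invalid target records:\n", paste(errs, collapse = "\n"))
    }
  }
  structure(list(category = category, records = records), class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat("target_set:", x$category, "with", length(x$records), "records\n")
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$records)

# serialize the optional scalar/vector metadata of a record into
# `key=value` tokens for the FASTA description line
.meta_tokens <- function(rec) {
  toks <- c(paste0("category=", rec$category))
  if (length(rec$genes)) toks <- c(toks, paste0("genes=", paste(rec$genes, collapse = ",")))
  if (length(rec$transcript_ids)) {
    toks <- c(toks, paste0("transcript_ids=", paste(rec$transcript_ids, collapse = ",")))
  }
  if (!is.null(rec$breakpoint_offset)) {
    toks <- c(toks, paste0("breakpoint_offset=", rec$breakpoint_offset))
  }
  if (!is.null(rec$codon_span)) {
    toks <- c(toks, paste0("codon_span=", paste(rec$codon_span, collapse = "-")))
  }
  if (!is.null(rec$frame_offset)) toks <- c(toks, paste0("frame_offset=", rec$frame_offset))
  if (!is.null(rec$codon_offset)) toks <- c(toks, paste0("codon_offset=", rec$codon_offset))
  if (nzchar(rec$notes)) toks <- c(toks, paste0("notes=", rec$notes))
  paste(toks, collapse = ";")
}

.parse_meta <- function(id, desc) {
  toks <- strsplit(desc, ";", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  kv <- strsplit(toks, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, character(1), 1L)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  names(vals) <- keys
  vals
}

#' Read a target FASTA with metadata headers
#'
#' The interchange format is plain FASTA; record metadata travels in the
#' description line as `key=value;` tokens (see [write_target_fasta()]).
#' All records are validated; malformed records abort the read with their ids
#' listed.
#'
#' @param path FASTA file path.
#' @param category expected category; records carrying a different category
#'   in their metadata are rejected.
#' @param k word length used for validation.
#' @return a `target_set`.
#' @export
read_target_fasta <- function(path, category, k = 31L) {
  category <- match.arg(category, TARGET_CATEGORIES)
  dna <- Biostrings::readDNAStringSet(path)
  if (!length(dna)) stop("empty target FASTA: ", path)
  headers <- names(dna)
  ids <- sub("\\s.*$", "", headers)
  descs <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  records <- vector("list", length(dna))
  for (i in seq_along(dna)) {
    meta <- if (nzchar(descs[i])) .parse_meta(ids[i], descs[i]) else character(0)
    get <- function(key) if (key %in% names(meta)) meta[[key]] else NULL
    cs <- get("codon_span")
    records[[i]] <- target_record(
      id = ids[i],
      category = if (!is.null(get("category"))) get("category") else category,
      sequence = as.character(dna[[i]]),
      genes = if (!is.null(get("genes"))) strsplit(get("genes"), ",")[[1]] else character(0),
      transcript_ids = if (!is.null(get("transcript_ids"))) {
        strsplit(get("transcript_ids"), ",")[[1]]
      } else character(0),
      breakpoint_offset = if (!is.null(get("breakpoint_offset"))) as.integer(get("breakpoint_offset")),
      codon_span = if (!is.null(cs)) as.integer(strsplit(cs, "-")[[1]]),
      frame_offset = if (!is.null(get("frame_offset"))) as.integer(get("frame_offset")),
      codon_offset = if (!is.null(get("codon_offset"))) as.integer(get("codon_offset")),
      notes = if (!is.null(get("notes"))) get("notes") else ""
    )
  }
  target_set(category, records, k = k)
}

#' Write a target set to FASTA
#'
#' Inverse of [read_target_fasta()]. Records are written sorted by id so the
#' output is deterministic; metadata goes into the description line.
#'
#' @param set a `target_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_target_fasta <- function(set, path) {
  stopifnot(inherits(set, "target_set"))
  recs <- set$records
  ord <- order(vapply(recs, function(r) r$id, character(1)), method = "radix")
  recs <- recs[ord]
  if (!length(recs)) {
    # empty set -> empty (still valid) FASTA file
    cat("", file = path)
    return(invisible(path))
  }
  dna <- Biostrings::DNAStringSet(vapply(recs, function(r) r$sequence, character(1)))
  names(dna) <- vapply(recs, function(r) paste(r$id, .meta_tokens(r)), character(1))
  Biostrings::writeXStringSet(dna, filepath = path, width = 80L)
  invisible(path)
}

#' Deduplicate targets by sequence
#'
#' Keeps the first record for each distinct sequence (records sorted by id
#' first, so the result is deterministic). Used when windows tiled from
#' several homologous source transcripts spell identical sequences.
#'
#' @param records list of `target_record`s.
#' @return filtered list.
#' @export
dedup_targets_by_sequence <- function(records) {
  ids <- vapply(records, function(r) r$id, character(1))
  records <- records[order(ids, method = "radix")]
  seqs <- vapply(records, function(r) r$sequence, character(1))
  records[!duplicated(seqs)]
}
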