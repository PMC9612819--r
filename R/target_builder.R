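#' @importFrom GenomicRanges GRanges strand start end seqnames
#' @importFrom IRanges IRanges
NULL

.as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  stopifnot(methods::is(genome, "DNAStringSet"))
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

.as_annotation <- function(annotation) {
  if (is.character(annotation) && length(annotation) == 1L) {
    annotation <- rtracklayer::import(annotation, format = "gtf")
  }
  stopifnot(methods::is(annotation, "GRanges"))
  annotation
}

#' Spliced transcript sequence with a genomic coordinate map
#'
#' Concatenates a transcript's exon (or CDS) features in transcription order,
#' reverse-complementing minus-strand transcripts, and returns alongside the
#' sequence a per-base map back to 1-based genomic positions and the exon
#' boundaries in transcript space. GTF coordinates are 1-based inclusive;
#' transcript-space offsets are 0-based half-open.
#'
#' @param genome a [Biostrings::DNAStringSet] or FASTA path.
#' @param annotation a [GenomicRanges::GRanges] (as from
#'   [rtracklayer::import]) or GTF path; must carry `type` and
#'   `transcript_id` metadata columns.
#' @param transcript_id transcript to extract.
#' @param feature feature type to splice: `"exon"` (default) or `"CDS"`.
#' @return list with `sequence` (character), `chrom`, `strand`, `map`
#'   (data.frame chrom/pos per transcript base), and `exons` (data.frame
#'   exon_number/tx_start/tx_end, transcript-space 0-based half-open).
#' @export
spliced_transcript_sequence <- function(genome, annotation, transcript_id,
                                        feature = c("exon", "CDS")) {
  feature <- match.arg(feature)
  genome <- .as_genome(genome)
  annotation <- .as_annotation(annotation)
  sel <- annotation$type == feature &
    !is.na(annotation$transcript_id) & annotation$transcript_id == transcript_id
  gr <- annotation[sel]
  if (!length(gr)) {
    stop("no ", feature, " features for transcript '", transcript_id,
         "' in the annotation")
  }
  chrom <- as.character(seqnames(gr))[1]
  strand_c <- as.character(strand(gr))[1]
  ord <- order(start(gr))
  if (strand_c == "-") ord <- rev(ord)
  gr <- gr[ord]
  chrom_seq <- genome[[chrom]]
  if (is.null(chrom_seq)) stop("chromosome '", chrom, "' absent from genome")
  pieces <- character(length(gr))
  pos_list <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    s <- start(gr)[i]; e <- end(gr)[i]
    piece <- as.character(Biostrings::subseq(chrom_seq, s, e))
    if (strand_c == "-") {
      piece <- revcomp(piece)
      pos_list[[i]] <- e:s
    } else {
      pos_list[[i]] <- s:e
    }
    pieces[i] <- piece
  }
  lens <- nchar(pieces)
  tx_end <- cumsum(lens)
  list(
    sequence = paste(pieces, collapse = ""),
    chrom = chrom,
    strand = strand_c,
    map = data.frame(chrom = chrom, pos = unlist(pos_list),
                     stringsAsFactors = FALSE),
    exons = data.frame(exon_number = seq_along(gr),
                       tx_start = c(0L, tx_end[-length(tx_end)]),
                       tx_end = tx_end)
  )
}

#' Build an exon-exon fusion junction target
#'
#' The target is the last `flank` transcript-sense bases of the donor exon
#' joined to the first `flank` bases of the acceptor exon: 62 bases with the
#' default 31-base halves, with the junction at offset 31. The reciprocal
#' fusion is built by the swapped invocation.
#'
#' @param genome,annotation as in [spliced_transcript_sequence()].
#' @param donor,acceptor lists with elements `gene`, `tx`, `exon` (exon
#'   numbers in transcription order, 1-based).
#' @param flank bases contributed by each side (default 31).
#' @return a fusion-category `target_record`.
#' @export
build_fusion_target <- function(genome, annotation, donor, acceptor,
                                flank = 31L) {
  dtx <- spliced_transcript_sequence(genome, annotation, donor$tx)
  atx <- spliced_transcript_sequence(genome, annotation, acceptor$tx)
  dex <- dtx$exons[dtx$exons$exon_number == donor$exon, ]
  aex <- atx$exons[atx$exons$exon_number == acceptor$exon, ]
  if (!nrow(dex)) stop("donor transcript has no exon ", donor$exon)
  if (!nrow(aex)) stop("acceptor transcript has no exon ", acceptor$exon)
  if (dex$tx_end - dex$tx_start < flank) {
    stop("donor exon ", donor$exon, " of ", donor$gene,
         " shorter than ", flank, "b")
  }
  if (aex$tx_end - aex$tx_start < flank) {
    stop("acceptor exon ", acceptor$exon, " of ", acceptor$gene,
         " shorter than ", flank, "b")
  }
  didx <- (dex$tx_end - flank + 1L):dex$tx_end           # 1-based tx indices
  aidx <- (aex$tx_start + 1L):(aex$tx_start + flank)
  seqc <- paste0(
    substr(dtx$sequence, didx[1], didx[flank]),
    substr(atx$sequence, aidx[1], aidx[flank])
  )
  target_record(
    id = sprintf("%s-%s_e%de%d", donor$gene, acceptor$gene,
                 donor$exon, acceptor$exon),
    category = "fusion",
    sequence = seqc,
    genes = c(donor$gene, acceptor$gene),
    transcript_ids = c(donor$tx, acceptor$tx),
    breakpoint_offset = flank,
    coord_map = rbind(dtx$map[didx, ], atx$map[aidx, ]),
    notes = sprintf("junction %s exon %d -> %s exon %d",
                    donor$gene, donor$exon, acceptor$gene, acceptor$exon)
  )
}

#' Build an in-frame SNV/InDel neighbourhood target
#'
#' Extracts the targeted codon(s) plus `flank` coding bases on either side
#' from the spliced CDS, so the target is in frame and its flanks cross
#' splice junctions where needed: a single codon gives a 69-base target, two
#' adjacent codons 72 bases (with the default 33-base flanks).
#'
#' @param genome,annotation as in [spliced_transcript_sequence()].
#' @param gene gene symbol (id/bookkeeping only).
#' @param tx coding transcript identifier (must have CDS features).
#' @param aa_start,aa_end 1-based amino-acid positions of interest.
#' @param flank coding bases on either side (default 33).
#' @return an snv-category `target_record` with `codon_span`,
#'   `frame_offset` and `codon_offset` recorded.
#' @export
build_snv_target <- function(genome, annotation, gene, tx, aa_start,
                             aa_end = aa_start, flank = 33L) {
  stopifnot(aa_start >= 1L, aa_start <= aa_end)
  cds <- tryCatch(
    spliced_transcript_sequence(genome, annotation, tx, feature = "CDS"),
    error = function(e) stop("transcript '", tx, "' is non-coding or lacks ",
                             "CDS features: ", conditionMessage(e)))
  nt0 <- 3L * (aa_start - 1L)               # 0-based CDS offset of first codon
  nt1 <- 3L * aa_end                        # exclusive end of last codon
  L <- nchar(cds$sequence)
  if (nt0 - flank < 0L || nt1 + flank > L) {
    stop("codons ", aa_start, "-", aa_end, " of ", gene,
         " too close to the transcript ends for ", flank, "b flanks")
  }
  idx <- (nt0 - flank + 1L):(nt1 + flank)   # 1-based CDS indices
  target_record(
    id = sprintf("%s_p%d%s", gene, aa_start,
                 if (aa_end > aa_start) sprintf("-%d", aa_end) else ""),
    category = "snv",
    sequence = substr(cds$sequence, idx[1], idx[length(idx)]),
    genes = gene,
    transcript_ids = tx,
    codon_span = c(aa_start, aa_end),
    frame_offset = flank %% 3L,
    codon_offset = flank,
    coord_map = cds$map[idx, ],
    notes = sprintf("codons %d-%d of %s", aa_start, aa_end, tx)
  )
}

#' Build an intragenic-deletion junction target
#'
#' Represents the aberrant transcript isoform produced by loss of internal
#' exons: the last `flank` bases of the exon preceding the deleted range
#' joined to the first `flank` bases of the exon following it (62 bases by
#' default). Deleted ranges touching the first or last exon have no junction
#' transcript and are rejected.
#'
#' @param genome,annotation as in [spliced_transcript_sequence()].
#' @param gene gene symbol.
#' @param tx transcript identifier.
#' @param del_start,del_end first and last deleted exon numbers (1-based,
#'   transcription order).
#' @param flank bases from each flanking exon (default 31).
#' @return a deletion-category `target_record`.
#' @export
build_deletion_target <- function(genome, annotation, gene, tx,
                                  del_start, del_end = del_start,
                                  flank = 31L) {
  stopifnot(del_start <= del_end)
  txs <- spliced_transcript_sequence(genome, annotation, tx)
  n <- nrow(txs$exons)
  if (del_start <= 1L || del_end >= n) {
    stop("deleted exon range ", del_start, "-", del_end,
         " touches the first or last exon of ", tx,
         "; the transcript would carry no junction")
  }
  lex <- txs$exons[txs$exons$exon_number == del_start - 1L, ]
  rex <- txs$exons[txs$exons$exon_number == del_end + 1L, ]
  if (lex$tx_end - lex$tx_start < flank) {
    stop("exon ", del_start - 1L, " of ", tx, " shorter than ", flank, "b")
  }
  if (rex$tx_end - rex$tx_start < flank) {
    stop("exon ", del_end + 1L, " of ", tx, " shorter than ", flank, "b")
  }
  lidx <- (lex$tx_end - flank + 1L):lex$tx_end
  ridx <- (rex$tx_start + 1L):(rex$tx_start + flank)
  target_record(
    id = sprintf("%s_del_e%d-%d", gene, del_start, del_end),
    category = "deletion",
    sequence = paste0(substr(txs$sequence, lidx[1], lidx[flank]),
                      substr(txs$sequence, ridx[1], ridx[flank])),
    genes = gene,
    transcript_ids = tx,
    breakpoint_offset = flank,
    coord_map = rbind(txs$map[lidx, ], txs$map[ridx, ]),
    notes = sprintf("exon %d | exon %d junction (exons %d-%d deleted)",
                    del_start - 1L, del_end + 1L, del_start, del_end)
  )
}

#' Tile expression-marker windows over a transcript region
#'
#' Splits the region `[1, region_end]` of the transcript, minus any excluded
#' intervals, into maximal kept intervals, then tiles each kept interval
#' left-to-right with non-overlapping windows of exactly `window` bases;
#' residual stretches shorter than a window are discarded. Used for
#' expression markers such as DUX4, whose rearrangements have variable
#' breakpoints but cause high-level expression of an otherwise silent
#' transcript. Identical windows arising from several homologous source
#' transcripts can be collapsed afterwards with
#' [dedup_targets_by_sequence()].
#'
#' @param transcript_sequence source transcript (character).
#' @param region_end last base of the tiled region (default 700).
#' @param window window width in bases (default 70; must be >= `k`).
#' @param exclusions list of 1-based inclusive `c(start, end)` intervals to
#'   omit (e.g. regions homologous to other genomic loci).
#' @param id_prefix prefix for window ids.
#' @param gene gene symbol recorded on each window.
#' @param k screening word length (validation only).
#' @return list of expression-category `target_record`s (possibly empty,
#'   with a warning, when the region is shorter than one window).
#' @export
build_expression_targets <- function(transcript_sequence, region_end = 700L,
                                     window = 70L,
                                     exclusions = list(c(141L, 210L)),
                                     id_prefix = "expr", gene = "",
                                     k = 31L) {
  stopifnot(window >= k)
  region_end <- min(region_end, nchar(transcript_sequence))
  if (region_end < window) {
    warning("region [1,", region_end, "] shorter than one ", window,
            "b window; no targets emitted")
    return(list())
  }
  kept <- IRanges::IRanges(start = 1L, end = region_end)
  if (length(exclusions)) {
    excl <- IRanges::IRanges(
      start = vapply(exclusions, `[`, integer(1), 1L),
      end = vapply(exclusions, `[`, integer(1), 2L))
    kept <- IRanges::setdiff(kept, excl)
  }
  records <- list()
  widx <- 0L
  for (i in seq_along(kept)) {
    s <- IRanges::start(kept)[i]; e <- IRanges::end(kept)[i]
    starts <- seq.int(s, by = window, length.out = (e - s + 1L) %/% window)
    for (ws in starts) {
      widx <- widx + 1L
      records[[length(records) + 1L]] <- target_record(
        id = sprintf("%s_w%02d", id_prefix, widx),
        category = "expression",
        sequence = substr(transcript_sequence, ws, ws + window - 1L),
        genes = gene,
        notes = sprintf("transcript window %d-%d", ws, ws + window - 1L)
      )
    }
  }
  records
}

#' Build immunoglobulin-rearrangement breakpoint targets
#'
#' IG-locus translocations (e.g. IGH-CRLF2, IGH-EPOR) have highly variable
#' breakpoints, so one target is emitted per IG allele: the `prefix_len`
#' partner-gene bases immediately 5' of the reported breakpoint joined to the
#' full allele sequence.
#'
#' @param partner_sequence partner-gene sequence (character) containing the
#'   breakpoint.
#' @param breakpoint_position 1-based position of the first partner base 3'
#'   of the breakpoint; bases `[breakpoint_position - prefix_len,
#'   breakpoint_position - 1]` form the shared prefix.
#' @param allele_fasta FASTA path, [Biostrings::DNAStringSet], or named
#'   character vector of IG allele sequences (IMGT-style headers tolerated;
#'   the first whitespace-delimited token is taken as the allele id).
#' @param partner_name partner label used in target ids.
#' @param prefix_len partner bases 5' of the breakpoint (default 50).
#' @return list of ig_rearrangement-category `target_record`s, one per
#'   allele.
#' @export
build_ig_targets <- function(partner_sequence, breakpoint_position,
                             allele_fasta, partner_name = "partner",
                             prefix_len = 50L) {
  if (is.character(allele_fasta) && length(allele_fasta) == 1L &&
      file.exists(allele_fasta)) {
    allele_fasta <- Biostrings::readDNAStringSet(allele_fasta)
  }
  alleles <- if (methods::is(allele_fasta, "DNAStringSet")) {
    stats::setNames(as.character(allele_fasta),
                    sub("\\s.*$", "", names(allele_fasta)))
  } else {
    allele_fasta
  }
  if (!length(alleles)) stop("empty allele set; no IG targets can be built")
  if (breakpoint_position - prefix_len < 1L) {
    stop("breakpoint too close to the partner sequence start (need ",
         prefix_len, " bases 5' of it)")
  }
  prefix <- substr(partner_sequence, breakpoint_position - prefix_len,
                   breakpoint_position - 1L)
  lapply(seq_along(alleles), function(i) {
    target_record(
      id = paste0(partner_name, "__", names(alleles)[i]),
      category = "ig_rearrangement",
      sequence = paste0(prefix, alleles[[i]]),
      genes = partner_name,
      breakpoint_offset = prefix_len,
      notes = sprintf("%db partner prefix + allele %s",
                      prefix_len, names(alleles)[i])
    )
  })
}

#' Add population-SNP alternate targets
#'
#' For every supplied population variant with allele frequency above the
#' threshold that falls inside the target's genomic span, emits an additional
#' target with the alternate base substituted, so a common SNP in a patient
#' cannot break the exact-match rule and cause a false negative. Variants at
#' or below the threshold, outside the span, or unmappable (no construction
#' coordinate map) are ignored; unmappable ones are logged.
#'
#' @param target a `target_record` carrying a construction `coord_map`.
#' @param variants data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `af` (single-nucleotide substitutions).
#' @param af_threshold allele-frequency threshold (default 0.01; strictly
#'   greater-than retained).
#' @return list of `target_record`s: the original followed by any alternates
#'   (ids suffixed with the SNP).
#' @export
add_snp_alternates <- function(target, variants, af_threshold = 0.01) {
  stopifnot(inherits(target, "target_record"))
  out <- list(target)
  if (is.null(variants) || !nrow(variants)) return(out)
  keep <- variants$af > af_threshold
  variants <- variants[keep, , drop = FALSE]
  if (!nrow(variants)) return(out)
  cm <- target$coord_map
  if (is.null(cm)) {
    message("note: target ", target$id,
            " has no coordinate map; population variants skipped")
    return(out)
  }
  for (r in seq_len(nrow(variants))) {
    hit <- which(cm$chrom == variants$chrom[r] & cm$pos == variants$pos[r])
    if (!length(hit)) next
    i <- hit[1]
    base <- substr(target$sequence, i, i)
    vref <- variants$ref[r]; valt <- variants$alt[r]
    if (base != vref && base != revcomp(vref)) {
      message("note: variant ", variants$chrom[r], ":", variants$pos[r],
              " ref allele does not match target ", target$id, "; skipped")
      next
    }
    sub_base <- if (base == vref) valt else revcomp(valt)
    alt_rec <- target
    alt_rec$sequence <- paste0(substr(target$sequence, 1L, i - 1L), sub_base,
                               substr(target$sequence, i + 1L,
                                      nchar(target$sequence)))
    alt_rec$id <- sprintf("%s_SNP_%s:%d%s>%s", target$id, variants$chrom[r],
                          variants$pos[r], vref, valt)
    alt_rec$notes <- paste0(target$notes, "; alternate with population SNP ",
                            variants$chrom[r], ":", variants$pos[r],
                            " (AF=", variants$af[r], ")")
    out[[length(out) + 1L]] <- alt_rec
  }
  out
}

#' Read a custom-target catalog specification
#'
#' Tab-separated, no header. Fusion rows have six fields (geneA, transcriptA,
#' exonA, geneB, transcriptB, exonB); variant rows have four (gene,
#' transcript, amino-acid start, amino-acid end); deletion rows have five
#' (gene, transcript, "del", first and last deleted exon). Row kinds are
#' distinguished by field count.
#'
#' @param path TSV path.
#' @return list with data.frames `fusions`, `variants`, `deletions`.
#' @export
read_catalog_spec <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  fus <- parts[nfield == 6L]
  vars <- parts[nfield == 4L]
  dels <- parts[nfield == 5L]
  bad <- which(!nfield %in% c(4L, 5L, 6L))
  if (length(bad)) {
    stop("unrecognized catalog rows (expected 4, 5 or 6 tab-separated ",
         "fields): lines ", paste(bad, collapse = ", "))
  }
  list(
    fusions = if (length(fus)) data.frame(
      geneA = vapply(fus, `[`, "", 1L), txA = vapply(fus, `[`, "", 2L),
      exonA = as.integer(vapply(fus, `[`, "", 3L)),
      geneB = vapply(fus, `[`, "", 4L), txB = vapply(fus, `[`, "", 5L),
      exonB = as.integer(vapply(fus, `[`, "", 6L)),
      stringsAsFactors = FALSE) else NULL,
    variants = if (length(vars)) data.frame(
      gene = vapply(vars, `[`, "", 1L), tx = vapply(vars, `[`, "", 2L),
      aa_start = as.integer(vapply(vars, `[`, "", 3L)),
      aa_end = as.integer(vapply(vars, `[`, "", 4L)),
      stringsAsFactors = FALSE) else NULL,
    deletions = if (length(dels)) data.frame(
      gene = vapply(dels, `[`, "", 1L), tx = vapply(dels, `[`, "", 2L),
      del_start = as.integer(vapply(dels, `[`, "", 4L)),
      del_end = as.integer(vapply(dels, `[`, "", 5L)),
      stringsAsFactors = FALSE) else NULL
  )
}

#' Read a population-variant list
#'
#' Tab-separated with header `chrom pos ref alt af`: single-nucleotide
#' substitutions with their population allele frequencies (e.g. exported
#' from gnomAD).
#'
#' @param path TSV path.
#' @return data.frame with those columns.
#' @export
read_population_variants <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "af")
  if (!all(need %in% names(df))) {
    stop("population-variant table must have columns: ",
         paste(need, collapse = ", "))
  }
  stopifnot(all(df$af >= 0 & df$af <= 1),
            all(nchar(df$ref) == 1L), all(nchar(df$alt) == 1L))
  df
}

#' Build a target catalog from a specification
#'
#' Applies the per-row builders and writes one FASTA per category into
#' `out_dir` (`fusion.fa`, `snv.fa`, `deletion.fa`), in deterministic order.
#' Per-row failures are collected and reported without aborting the batch.
#'
#' @param genome,annotation as in [spliced_transcript_sequence()].
#' @param catalog_spec result of [read_catalog_spec()] (or a path to one).
#' @param out_dir output directory (created if needed).
#' @param variants optional population-variant data.frame (see
#'   [add_snp_alternates()]); applied to fusion and snv targets.
#' @param af_threshold allele-frequency threshold for alternates.
#' @param k screening word length used for validation.
#' @return list with `sets` (named list of `target_set`s), `files` and
#'   `errors` (character vector of per-row failure messages).
#' @export
build_catalog <- function(genome, annotation, catalog_spec, out_dir,
                          variants = NULL, af_threshold = 0.01, k = 31L) {
  if (is.character(catalog_spec)) catalog_spec <- read_catalog_spec(catalog_spec)
  genome <- .as_genome(genome)
  annotation <- .as_annotation(annotation)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  errors <- character(0)
  recs <- list(fusion = list(), snv = list(), deletion = list())
  with_alternates <- function(rec) {
    if (is.null(variants)) list(rec) else {
      add_snp_alternates(rec, variants, af_threshold)
    }
  }
  sp <- catalog_spec
  if (!is.null(sp$fusions)) for (r in seq_len(nrow(sp$fusions))) {
    row <- sp$fusions[r, ]
    res <- tryCatch({
      rec <- build_fusion_target(
        genome, annotation,
        donor = list(gene = row$geneA, tx = row$txA, exon = row$exonA),
        acceptor = list(gene = row$geneB, tx = row$txB, exon = row$exonB))
      recs$fusion <- c(recs$fusion, with_alternates(rec))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors <- c(errors, paste0("fusion row ", r, ": ", res))
  }
  if (!is.null(sp$variants)) for (r in seq_len(nrow(sp$variants))) {
    row <- sp$variants[r, ]
    res <- tryCatch({
      rec <- build_snv_target(genome, annotation, row$gene, row$tx,
                              row$aa_start, row$aa_end)
      recs$snv <- c(recs$snv, with_alternates(rec))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors <- c(errors, paste0("variant row ", r, ": ", res))
  }
  if (!is.null(sp$deletions)) for (r in seq_len(nrow(sp$deletions))) {
    row <- sp$deletions[r, ]
    res <- tryCatch({
      rec <- build_deletion_target(genome, annotation, row$gene, row$tx,
                                   row$del_start, row$del_end)
      recs$deletion <- c(recs$deletion, list(rec))
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) errors <- c(errors, paste0("deletion row ", r, ": ", res))
  }
  sets <- list()
  files <- character(0)
  for (cat in names(recs)) {
    if (!length(recs[[cat]])) next
    set <- target_set(cat, recs[[cat]], k = k)
    path <- file.path(out_dir, paste0(cat, ".fa"))
    write_target_fasta(set, path)
    sets[[cat]] <- set
    files <- c(files, path)
  }
  list(sets = sets, files = files, errors = errors)
}
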