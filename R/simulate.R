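# run fn with a private RNG stream so simulation never perturbs (or depends
# on) the caller's RNG state
.with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a toy genome and matching GTF annotation
#'
#' Places the requested genes end-to-end (with spacers, so placements can
#' never overlap) on a single synthetic chromosome and writes a genome FASTA
#' plus a GTF with gene/transcript/exon/CDS features consistent with it.
#' Every exon is marked coding (CDS spanning the exon) so amino-acid
#' coordinates resolve on toy transcripts. Deterministic for a given seed.
#'
#' @param genes list of gene specs: `list(name=, strand=("+"/"-"),
#'   exon_lengths=, intron_lengths=)` with `length(intron_lengths) ==
#'   length(exon_lengths) - 1` and every exon >= 31 bases.
#' @param seed integer seed for the base composition.
#' @param out_prefix optional path prefix; when given, writes
#'   `<prefix>.fa` and `<prefix>.gtf`.
#' @param chrom chromosome name (default `"chrT"`).
#' @param spacer intergenic gap in bases (default 100).
#' @return list with `genome` (DNAStringSet), `annotation` (GRanges), and
#'   `fasta`/`gtf` paths when written.
#' @export
make_toy_genome <- function(genes, seed = 1L, out_prefix = NULL,
                            chrom = "chrT", spacer = 100L) {
  nm <- vapply(genes, function(g) g$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate gene names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  for (g in genes) {
    stopifnot(all(g$exon_lengths >= 31L),
              length(g$intron_lengths) == length(g$exon_lengths) - 1L,
              g$strand %in% c("+", "-"))
  }
  .with_seed(seed, function() {
    cursor <- spacer
    feats <- list()
    pieces <- character(0)
    pieces_end <- 0L
    for (g in genes) {
      ne <- length(g$exon_lengths)
      glen <- sum(g$exon_lengths) + sum(g$intron_lengths)
      gstart <- cursor + 1L
      # fill sequence up to the gene body
      pieces <- c(pieces, .random_dna(gstart - pieces_end - 1L + glen))
      pieces_end <- gstart - 1L + glen
      # exon genomic intervals, left to right
      ex_start <- gstart
      starts <- integer(ne); ends <- integer(ne)
      for (i in seq_len(ne)) {
        starts[i] <- ex_start
        ends[i] <- ex_start + g$exon_lengths[i] - 1L
        if (i < ne) ex_start <- ends[i] + g$intron_lengths[i] + 1L
      }
      # exon numbers follow transcription order
      exon_number <- if (g$strand == "+") seq_len(ne) else rev(seq_len(ne))
      tx_id <- paste0(g$name, ".t1")
      # GTF frame/phase: bases to skip before the first complete codon,
      # accumulated over the preceding CDS in transcription order
      len_tx_order <- g$exon_lengths[order(exon_number)]
      prior <- c(0L, cumsum(len_tx_order))[seq_len(ne)]
      phase_tx <- (3L - prior %% 3L) %% 3L
      phase <- phase_tx[exon_number]          # back to genomic order
      feats[[length(feats) + 1L]] <- data.frame(
        start = c(gstart, gstart, starts, starts),
        end = c(max(ends), max(ends), ends, ends),
        type = c("gene", "transcript", rep("exon", ne), rep("CDS", ne)),
        strand = g$strand,
        gene_id = g$name, gene_name = g$name,
        transcript_id = c(NA, tx_id, rep(tx_id, 2L * ne)),
        exon_number = c(NA, NA, exon_number, exon_number),
        phase = c(rep(NA_integer_, 2L + ne), phase),
        stringsAsFactors = FALSE)
      cursor <- pieces_end + spacer
    }
    pieces <- c(pieces, .random_dna(spacer))
    chrom_seq <- paste(pieces, collapse = "")
    genome <- Biostrings::DNAStringSet(stats::setNames(chrom_seq, chrom))
    fdf <- do.call(rbind, feats)
    annotation <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = fdf$start, end = fdf$end),
      strand = fdf$strand)
    annotation$type <- fdf$type
    annotation$gene_id <- fdf$gene_id
    annotation$gene_name <- fdf$gene_name
    annotation$transcript_id <- fdf$transcript_id
    annotation$exon_number <- fdf$exon_number
    annotation$phase <- fdf$phase
    annotation$source <- "kmerscreen_toy"
    res <- list(genome = genome, annotation = annotation)
    if (!is.null(out_prefix)) {
      fasta <- paste0(out_prefix, ".fa")
      gtf <- paste0(out_prefix, ".gtf")
      Biostrings::writeXStringSet(genome, fasta, width = 80L)
      rtracklayer::export(annotation, gtf, format = "gtf")
      res$fasta <- fasta
      res$gtf <- gtf
    }
    res
  })
}

#' Apply a structured edit to a transcript sequence
#'
#' Pure function implementing the alteration types the screen must detect:
#' point substitutions, insertions, deletions, exon-skips (removal of a
#' stated interval) and fusion-joins (donor prefix + acceptor suffix at
#' stated breakpoints).
#'
#' @param sequence transcript sequence.
#' @param edit a list with element `type` plus, depending on type:
#'   `substitution`: `pos` (1-based), `alt` (replacement base(s));
#'   `insertion`: `pos` (inserted after this 1-based position), `alt`;
#'   `deletion`/`exon_skip`: `start`, `end` (1-based inclusive interval
#'   removed);
#'   `fusion_join`: `breakpoint` (last donor base kept), `acceptor`
#'   (sequence), `acceptor_start` (first acceptor base used, default 1).
#' @return edited sequence.
#' @export
mutate_transcript <- function(sequence, edit) {
  n <- nchar(sequence)
  switch(edit$type,
    substitution = {
      w <- nchar(edit$alt)
      stopifnot(edit$pos >= 1L, edit$pos + w - 1L <= n)
      paste0(substr(sequence, 1L, edit$pos - 1L), edit$alt,
             substr(sequence, edit$pos + w, n))
    },
    insertion = {
      stopifnot(edit$pos >= 0L, edit$pos <= n)
      paste0(substr(sequence, 1L, edit$pos), edit$alt,
             substr(sequence, edit$pos + 1L, n))
    },
    deletion = ,
    exon_skip = {
      stopifnot(edit$start >= 1L, edit$end >= edit$start, edit$end <= n)
      paste0(substr(sequence, 1L, edit$start - 1L),
             substr(sequence, edit$end + 1L, n))
    },
    fusion_join = {
      astart <- if (is.null(edit$acceptor_start)) 1L else edit$acceptor_start
      paste0(substr(sequence, 1L, edit$breakpoint),
             substr(edit$acceptor, astart, nchar(edit$acceptor)))
    },
    stop("unknown edit type: ", edit$type)
  )
}

#' Simulation sample specification
#'
#' @param transcripts data.frame with columns `id`, `sequence`, `abundance`
#'   (relative, >= 0, not all zero).
#' @param read_length read length in bases (default 75, typical short-read
#'   RNA-seq).
#' @param n_reads number of reads (pairs, when `paired`).
#' @param paired emit proper mate pairs (default FALSE).
#' @param fragment_mean,fragment_sd fragment-length distribution for paired
#'   mode (defaults 200/20).
#' @param error_rate per-base substitution error probability in [0,1)
#'   (default 0).
#' @param seed integer seed.
#' @return an object of class `sim_sample_spec`.
#' @export
sim_sample_spec <- function(transcripts, read_length = 75L, n_reads = 1000L,
                            paired = FALSE, fragment_mean = 200,
                            fragment_sd = 20, error_rate = 0, seed = 1L) {
  stopifnot(is.data.frame(transcripts),
            all(c("id", "sequence", "abundance") %in% names(transcripts)),
            all(transcripts$abundance >= 0), sum(transcripts$abundance) > 0,
            error_rate >= 0, error_rate < 1)
  if (any(nchar(transcripts$sequence) < read_length)) {
    stop("read_length exceeds the length of at least one transcript")
  }
  structure(list(transcripts = transcripts,
                 read_length = as.integer(read_length),
                 n_reads = as.integer(n_reads), paired = isTRUE(paired),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 error_rate = error_rate, seed = as.integer(seed)),
            class = "sim_sample_spec")
}

.apply_errors <- function(reads, error_rate) {
  if (error_rate <= 0) return(reads)
  vapply(reads, function(r) {
    n <- nchar(r)
    hit <- which(stats::runif(n) < error_rate)
    if (!length(hit)) return(r)
    ch <- strsplit(r, "", fixed = TRUE)[[1]]
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1L)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate RNA-seq reads from a transcript mixture
#'
#' Reads are drawn from transcripts proportional to abundance with uniform
#' start positions and independent per-base substitution errors; paired mode
#' draws a fragment per pair and emits mate 1 from the fragment start and
#' mate 2 reverse-complemented from the fragment end. Reproducible for a
#' given seed. Quality strings are constant (maximal), since k-mer counting
#' ignores them.
#'
#' @param spec a [sim_sample_spec()].
#' @param out_prefix optional path prefix; writes `<prefix>_R1.fastq` (and
#'   `_R2` when paired).
#' @param gzip write gzipped FASTQ (default FALSE).
#' @return list with `reads` (character vector; both mates pooled),
#'   `mate1`/`mate2`, `origin` (transcript index per read/pair) and any
#'   written `files`.
#' @export
simulate_reads <- function(spec, out_prefix = NULL, gzip = FALSE) {
  stopifnot(inherits(spec, "sim_sample_spec"))
  tx <- spec$transcripts
  rl <- spec$read_length
  .with_seed(spec$seed, function() {
    origin <- sample.int(nrow(tx), spec$n_reads, replace = TRUE,
                         prob = tx$abundance / sum(tx$abundance))
    lens <- nchar(tx$sequence)[origin]
    if (spec$paired) {
      frag <- pmin(pmax(round(stats::rnorm(spec$n_reads, spec$fragment_mean,
                                           spec$fragment_sd)), rl), lens)
      starts <- floor(stats::runif(spec$n_reads) * (lens - frag + 1L)) + 1L
      m1 <- substr(tx$sequence[origin], starts, starts + rl - 1L)
      m2 <- revcomp(substr(tx$sequence[origin], starts + frag - rl,
                           starts + frag - 1L))
    } else {
      starts <- floor(stats::runif(spec$n_reads) * (lens - rl + 1L)) + 1L
      m1 <- substr(tx$sequence[origin], starts, starts + rl - 1L)
      m2 <- NULL
    }
    m1 <- .apply_errors(m1, spec$error_rate)
    if (!is.null(m2)) m2 <- .apply_errors(m2, spec$error_rate)
    res <- list(reads = c(m1, m2), mate1 = m1, mate2 = m2, origin = origin)
    if (!is.null(out_prefix)) {
      write_fq <- function(seqs, path, suffix) {
        con <- if (gzip) gzfile(path, "w") else file(path, "w")
        on.exit(close(con))
        qual <- strrep("I", rl)
        ids <- sprintf("@sim_%06d%s", seq_along(seqs), suffix)
        writeLines(rbind(ids, seqs, "+", qual), con)
        path
      }
      ext <- if (gzip) ".fastq.gz" else ".fastq"
      f1 <- write_fq(m1, paste0(out_prefix, "_R1", ext), "/1")
      res$files <- f1
      if (!is.null(m2)) {
        f2 <- write_fq(m2, paste0(out_prefix, "_R2", ext), "/2")
        res$files <- c(f1, f2)
      }
    }
    res
  })
}
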