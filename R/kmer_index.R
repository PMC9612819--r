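#' @importFrom stringi stri_reverse stri_sub
#' @importFrom methods is
NULL

#' Reverse complement of nucleotide words
#'
#' Plain-character reverse complement, vectorised. Only A/C/G/T are mapped;
#' anything else passes through `chartr` unchanged (callers are expected to
#' have filtered non-ACGT words already).
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGT", "TGCA", x))
}

#' Collapse words with their reverse complements
#'
#' The canonical form of a word is the lexicographically smaller of the word
#' and its reverse complement, so counting is strand-agnostic.
#'
#' @param x character vector of ACGT words.
#' @return character vector of canonical words.
#' @keywords internal
canonicalize <- function(x) {
  rc <- revcomp(x)
  ifelse(x <= rc, x, rc)
}

#' Build a k-mer count table from reads
#'
#' Decomposes every read into its length-`k` windows and tabulates their
#' multiplicities. Both mates of a read pair are treated as independent reads;
#' windows containing any non-ACGT symbol are skipped (the rest of the read is
#' still counted). With `canonical = TRUE` each window is collapsed with its
#' reverse complement before counting, so detection does not depend on the
#' strandedness of the library prep.
#'
#' @param reads character vector of read sequences, or a
#'   [Biostrings::DNAStringSet], or a (list of) FASTQ file path(s) read via
#'   [read_fastq_reads()].
#' @param k integer word length in bases (>= 2). Default 31.
#' @param canonical logical; collapse each window with its reverse complement
#'   (default `TRUE`).
#' @return An object of class `kmer_count_table`: a list with elements `k`,
#'   `canonical`, `counts` (a hashed environment mapping word to count) and
#'   `total_words` (sum of all counts).
#' @examples
#' tab <- count_kmers(c("ACGTACGTAC"), k = 4)
#' kmer_counts(tab)
#' @export
count_kmers <- function(reads, k = 31L, canonical = TRUE) {
  if (methods::is(reads, "DNAStringSet")) reads <- as.character(reads)
  stopifnot(is.character(reads), length(k) == 1L, k >= 2L)
  k <- as.integer(k)
  reads <- toupper(reads)
  words <- character(0)
  if (length(reads)) {
    lens <- nchar(reads)
    if (all(lens < k) && length(reads) > 0L) {
      warning("k = ", k, " exceeds every read length; count table is empty")
    }
    keep <- lens >= k
    words <- unlist(lapply(reads[keep], function(r) {
      n <- nchar(r)
      substring(r, 1:(n - k + 1L), k:n)
    }), use.names = FALSE)
    if (length(words)) {
      words <- words[!grepl("[^ACGT]", words)]
    }
    if (canonical && length(words)) words <- canonicalize(words)
  }
  counts <- new.env(parent = emptyenv(), hash = TRUE,
                    size = max(29L, length(words)))
  if (length(words)) {
    tab <- table(words)
    nm <- names(tab)
    cnt <- as.integer(tab)
    for (i in seq_along(nm)) assign(nm[i], cnt[i], envir = counts)
  }
  structure(
    list(k = k, canonical = isTRUE(canonical), counts = counts,
         total_words = length(words)),
    class = "kmer_count_table"
  )
}

#' @export
print.kmer_count_table <- function(x, ...) {
  cat("kmer_count_table: k =", x$k,
      "| canonical =", x$canonical,
      "| distinct words =", length(ls(x$counts)),
      "| total words =", x$total_words, "\n")
  invisible(x)
}

#' Look up counts for a set of words
#'
#' Queries respect the table's canonicalization policy: with a canonical
#' table, each query word is collapsed with its reverse complement before
#' lookup. Absent words return 0.
#'
#' @param table a `kmer_count_table`.
#' @param words character vector of length-`k` words.
#' @return integer vector of counts, one per query word.
#' @export
kmer_lookup <- function(table, words) {
  stopifnot(inherits(table, "kmer_count_table"))
  if (!length(words)) return(integer(0))
  if (table$canonical) words <- canonicalize(words)
  as.integer(unlist(
    mget(words, envir = table$counts, ifnotfound = 0L),
    use.names = FALSE
  ))
}

#' Extract the full count table as a sorted named vector
#'
#' @param table a `kmer_count_table`.
#' @return named integer vector of counts, sorted by word.
#' @export
kmer_counts <- function(table) {
  stopifnot(inherits(table, "kmer_count_table"))
  nm <- sort(ls(table$counts))
  if (!length(nm)) return(stats::setNames(integer(0), character(0)))
  stats::setNames(
    as.integer(unlist(mget(nm, envir = table$counts), use.names = FALSE)),
    nm
  )
}

#' Target windows
#'
#' All length-k windows of a sequence, in order.
#' @keywords internal
seq_windows <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) stop("sequence shorter than k = ", k, "; unusable target")
  substring(sequence, 1:(n - k + 1L), k:n)
}

#' Minimum k-mer coverage of a target
#'
#' The smallest count, over all length-k windows of the target sequence,
#' observed in the sample's count table — the primary evidence statistic for
#' targeted screening. Returns 0 as soon as any window is absent.
#'
#' @param table a `kmer_count_table`.
#' @param target a `target_record` (see [target_record()]) or a plain
#'   character sequence.
#' @return integer minimum per-window count.
#' @export
min_coverage <- function(table, target) {
  stopifnot(inherits(table, "kmer_count_table"))
  sequence <- if (inherits(target, "target_record")) target$sequence else target
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < table$k) {
    stop("target shorter than k = ", table$k, "; unusable target")
  }
  min(kmer_lookup(table, seq_windows(sequence, table$k)))
}

#' Read FASTQ reads as plain sequences
#'
#' Thin wrapper around [Biostrings::readDNAStringSet] that accepts one file
#' (single-end) or two (paired-end); mates are pooled, since counting treats
#' them as independent reads. Gzipped files are handled transparently.
#'
#' @param files character vector of one or two FASTQ(.gz) paths.
#' @return character vector of read sequences.
#' @export
read_fastq_reads <- function(files) {
  stopifnot(is.character(files), length(files) >= 1L)
  seqs <- lapply(files, function(f) {
    as.character(Biostrings::readDNAStringSet(f, format = "fastq"))
  })
  unname(unlist(seqs))
}

#' Serialize a count table to a plain-text dump
#'
#' Versioned, self-describing format: comment header lines carry the format
#' version, k and the canonicalization policy, followed by word<TAB>count
#' lines sorted by word.
#'
#' @param table a `kmer_count_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_kmer_table <- function(table, path) {
  stopifnot(inherits(table, "kmer_count_table"))
  cnt <- kmer_counts(table)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "#kmerscreen_count_table\tv1",
    paste0("#k\t", table$k),
    paste0("#canonical\t", ifelse(table$canonical, "true", "false"))
  ), con)
  if (length(cnt)) {
    writeLines(paste(names(cnt), cnt, sep = "\t"), con)
  }
  invisible(path)
}

#' Load a count table from a plain-text dump
#'
#' @param path file written by [write_kmer_table()].
#' @return a `kmer_count_table`.
#' @export
read_kmer_table <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#kmerscreen_count_table")) {
    stop("not a kmerscreen count-table dump: ", path)
  }
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#")]
  get_field <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key, "\t"))]
    if (!length(ln)) stop("count-table dump missing header field: ", key)
    strsplit(ln[1], "\t", fixed = TRUE)[[1]][2]
  }
  k <- as.integer(get_field("k"))
  canonical <- identical(get_field("canonical"), "true")
  counts <- new.env(parent = emptyenv(), hash = TRUE,
                    size = max(29L, length(body)))
  total <- 0L
  for (ln in body) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    assign(parts[1], as.integer(parts[2]), envir = counts)
    total <- total + as.integer(parts[2])
  }
  structure(
    list(k = k, canonical = canonical, counts = counts, total_words = total),
    class = "kmer_count_table"
  )
}
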