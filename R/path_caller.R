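#' Construct a path call
#'
#' One assembled walk across a target: either the reference path (the target
#' spelled exactly), a divergent path that departs from and rejoins the
#' target (substitution, insertion, deletion, or several changes), or Absent
#' when no start-to-end walk exists in the sample's k-mer table.
#'
#' `ratio` is `min_coverage / (min_coverage + ref_min_coverage)` when the
#' denominator is positive, else 1.0; with reads spanning the whole target it
#' approximates the variant allele fraction.
#'
#' @keywords internal
path_call <- function(target_id, path_type, alt_sequence, variants,
                      min_coverage, ref_min_coverage) {
  denom <- min_coverage + ref_min_coverage
  structure(
    list(target_id = target_id,
         path_type = path_type,
         alt_sequence = alt_sequence,
         variants = variants,
         min_coverage = as.integer(min_coverage),
         ref_min_coverage = as.integer(ref_min_coverage),
         ratio = if (denom > 0) min_coverage / denom else 1.0),
    class = "path_call"
  )
}

.empty_variants <- function() {
  data.frame(pos = integer(0), ref = character(0), alt = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.path_call <- function(x, ...) {
  cat(sprintf("path_call %s [%s] min_cov=%d ref_min_cov=%d ratio=%.3f\n",
              x$target_id, x$path_type, x$min_coverage,
              x$ref_min_coverage, x$ratio))
  if (nrow(x$variants)) {
    cat("  variants:",
        paste(sprintf("%d:%s>%s", x$variants$pos, x$variants$ref, x$variants$alt),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Flatten path calls to a data frame
#'
#' @param calls list of `path_call`s.
#' @return data.frame with one row per call; variants rendered as an
#'   HGVS-like nucleotide string (`pos` 0-based).
#' @export
path_calls_df <- function(calls) {
  if (!length(calls)) {
    return(data.frame(target_id = character(0), path_type = character(0),
                      variants = character(0), min_coverage = integer(0),
                      ref_min_coverage = integer(0), ratio = numeric(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(calls, function(p) {
    v <- p$variants
    vstr <- if (nrow(v)) {
      paste(vapply(seq_len(nrow(v)), function(i) {
        if (nchar(v$ref[i]) && nchar(v$alt[i])) {
          sprintf("%d%s>%s", v$pos[i], v$ref[i], v$alt[i])
        } else if (nchar(v$alt[i])) {
          sprintf("%dins%s", v$pos[i], v$alt[i])
        } else {
          sprintf("%ddel%s", v$pos[i], v$ref[i])
        }
      }, character(1)), collapse = ";")
    } else ""
    data.frame(target_id = p$target_id, path_type = p$path_type,
               variants = vstr, min_coverage = p$min_coverage,
               ref_min_coverage = p$ref_min_coverage, ratio = p$ratio,
               stringsAsFactors = FALSE)
  }))
}

#' Exact-presence detection of a target
#'
#' A target is called present only when every one of its length-k windows is
#' observed in the count table at least `min_count` times — the exact-match
#' rule used for fusion junction and expression-window targets. A single SNP
#' inside the first or final window of the target therefore yields
#' non-detection when no exact-match reads exist (the principal
#' false-negative mechanism of junction screening).
#'
#' @param table a `kmer_count_table`.
#' @param target a `target_record` or plain sequence.
#' @param min_count minimum per-window count (>= 1).
#' @return list with `present` (logical) and `min_cov` (integer).
#' @export
detect_presence <- function(table, target, min_count = 1L) {
  stopifnot(min_count >= 1L)
  mc <- min_coverage(table, target)
  list(present = mc >= min_count, min_cov = mc)
}

#' Assemble reference and divergent paths across a target
#'
#' Walks the de Bruijn–style word graph implied by the count table, anchored
#' at the target's first and last windows. Successors of a window are the up
#' to four words obtained by appending one base to its (k-1)-suffix whose
#' count is at least `min_count`. The walk follows the target's own window
#' sequence and opens a branch wherever an off-target successor exists (or
#' the target's next window is absent); a branch completes when it re-enters
#' any target window downstream of the divergence point and the remaining
#' target windows are all present, and is abandoned when its assembled length
#' exceeds `target length + max_extra_length`, when it revisits a word more
#' than `max_cycle` times, or when the global branch budget is exhausted.
#'
#' Results are deduplicated by assembled sequence; the Reference path is
#' always included when every target window is present. Budget exhaustion is
#' not an error: the returned list carries a logical `truncated` attribute.
#'
#' @param table a `kmer_count_table`.
#' @param target a `target_record` (or plain sequence; a synthetic id is used).
#' @param min_count minimum count for a word to enter the graph (default 1;
#'   clinical thresholds are applied downstream at reporting).
#' @param max_extra_length maximum excess of an assembled path over the
#'   target length, in bases (default 60).
#' @param max_branches global branch budget per target (default 1000).
#' @param max_cycle maximum visits of one word within a branch (default 2).
#' @return list of `path_call`s (possibly a single Absent call), with
#'   attribute `truncated`.
#' @export
walk_paths <- function(table, target, min_count = 1L,
                       max_extra_length = 60L, max_branches = 1000L,
                       max_cycle = 2L) {
  stopifnot(inherits(table, "kmer_count_table"), min_count >= 1L)
  if (inherits(target, "target_record")) {
    tid <- target$id
    seqc <- target$sequence
  } else {
    tid <- "target"
    seqc <- as.character(target)
  }
  k <- table$k
  L <- nchar(seqc)
  if (L < k) stop("target shorter than k = ", k, "; unusable target")
  m <- L - k + 1L
  tw <- seq_windows(seqc, k)
  cnt_t <- kmer_lookup(table, tw)
  present <- cnt_t >= min_count
  ref_min_cov <- if (all(present)) min(cnt_t) else 0L

  # window -> target positions (repeats within the target map to several)
  wpos <- new.env(parent = emptyenv(), hash = TRUE, size = max(29L, m))
  for (i in seq_len(m)) {
    assign(tw[i], c(get0(tw[i], envir = wpos, ifnotfound = integer(0)), i),
           envir = wpos)
  }
  # tail_ok[j]: the target can be followed from window j to the end
  tail_ok <- rev(cumprod(rev(present)) == 1)

  found <- new.env(parent = emptyenv())   # alt_sequence -> TRUE
  alt_seqs <- character(0)
  if (all(present)) alt_seqs <- seqc

  truncated <- FALSE
  branches_used <- 0L
  bases <- c("A", "C", "G", "T")

  if (present[1]) {
    reach <- if (all(present)) m else which(!present)[1] - 1L
    # divergence points: every prefix window reachable along the reference
    stack <- list()
    for (i in seq_len(max(0L, min(reach, m - 1L)))) {
      suffix <- substr(tw[i], 2L, k)
      cand <- paste0(suffix, bases)
      ccnt <- kmer_lookup(table, cand)
      ok <- ccnt >= min_count & cand != tw[i + 1L]
      for (w in cand[ok]) {
        if (branches_used >= max_branches) { truncated <- TRUE; break }
        branches_used <- branches_used + 1L
        visits <- stats::setNames(1L, w)
        stack[[length(stack) + 1L]] <- list(i0 = i, appended = substr(w, k, k),
                                            word = w, visits = visits)
      }
      if (truncated) break
    }
    while (length(stack)) {
      st <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      # rejoin: current word matches a target window downstream of divergence
      # and the target is walkable from there to the end
      hits <- get0(st$word, envir = wpos, ifnotfound = integer(0))
      hits <- hits[hits > st$i0 & tail_ok[hits]]
      if (length(hits)) {
        j <- min(hits)
        alt <- paste0(substr(seqc, 1L, st$i0 + k - 1L), st$appended,
                      substr(seqc, j + k, L))
        alt_seqs <- c(alt_seqs, alt)
        next
      }
      if (st$i0 + k - 1L + nchar(st$appended) > L + max_extra_length) next
      suffix <- substr(st$word, 2L, k)
      cand <- paste0(suffix, bases)
      ccnt <- kmer_lookup(table, cand)
      keep <- which(ccnt >= min_count)
      first <- TRUE
      for (ci in keep) {
        w <- cand[ci]
        nvis <- if (w %in% names(st$visits)) st$visits[[w]] else 0L
        if (nvis >= max_cycle) next
        if (!first) {
          if (branches_used >= max_branches) { truncated <- TRUE; break }
          branches_used <- branches_used + 1L
        }
        first <- FALSE
        visits <- st$visits
        visits[w] <- nvis + 1L
        stack[[length(stack) + 1L]] <- list(
          i0 = st$i0, appended = paste0(st$appended, substr(w, k, k)),
          word = w, visits = visits)
      }
      if (truncated) break
    }
  }

  alt_seqs <- unique(alt_seqs)
  calls <- lapply(alt_seqs, function(alt) {
    mc <- min(kmer_lookup(table, seq_windows(alt, k)))
    cl <- classify_path(alt, seqc, k = k)
    path_call(tid, cl$path_type, alt, cl$variants, mc, ref_min_cov)
  })
  # deterministic order: Reference first, then by assembled sequence
  if (length(calls) > 1L) {
    ord <- order(vapply(calls, function(p) p$path_type != "Reference", logical(1)),
                 vapply(calls, function(p) p$alt_sequence, character(1)),
                 method = "radix")
    calls <- calls[ord]
  }
  if (!length(calls)) {
    calls <- list(path_call(tid, "Absent", "", .empty_variants(), 0L, ref_min_cov))
  }
  attr(calls, "truncated") <- truncated
  calls
}

# unit-cost global alignment (Needleman-Wunsch) of ref vs alt; returns the
# aligned operation string over columns: M (consume both), D (ref only),
# I (alt only). Traceback prefers M, then D, then I; indels are
# left-normalized afterwards, which makes the result deterministic and
# places every indel at its leftmost equivalent position.
.edit_align <- function(ref, alt) {
  a <- strsplit(ref, "", fixed = TRUE)[[1]]
  b <- strsplit(alt, "", fixed = TRUE)[[1]]
  n <- length(a); m <- length(b)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    sub_cost <- as.integer(a[i] != b)           # vector over j
    row_prev <- D[i, ]
    row <- integer(m + 1L)
    row[1L] <- i
    for (j in seq_len(m)) {
      row[j + 1L] <- min(row_prev[j] + sub_cost[j],  # diag
                         row_prev[j + 1L] + 1L,      # up: delete ref base
                         row[j] + 1L)                # left: insert alt base
    }
    D[i + 1L, ] <- row
  }
  # traceback; ties prefer continuing the gap begun to the right (fewest gap
  # openings), then the diagonal
  ops <- character(0)
  i <- n; j <- m
  last <- "M"
  while (i > 0L || j > 0L) {
    can_m <- i > 0L && j > 0L &&
      D[i + 1L, j + 1L] == D[i, j] + as.integer(a[i] != b[j])
    can_d <- i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L
    can_i <- j > 0L && D[i + 1L, j + 1L] == D[i + 1L, j] + 1L
    op <- if (last == "D" && can_d) "D"
          else if (last == "I" && can_i) "I"
          else if (can_m) "M"
          else if (can_d) "D"
          else "I"
    ops <- c(op, ops)
    if (op %in% c("M", "D")) i <- i - 1L
    if (op %in% c("M", "I")) j <- j - 1L
    last <- op
  }
  ops
}

# extract maximal non-match runs from an alignment as variant records
.alignment_variants <- function(ref, alt, ops) {
  a <- strsplit(ref, "", fixed = TRUE)[[1]]
  b <- strsplit(alt, "", fixed = TRUE)[[1]]
  i <- 0L; j <- 0L
  pos <- integer(0); refs <- character(0); alts <- character(0)
  in_run <- FALSE
  for (op in ops) {
    is_diff <- switch(op,
                      M = { di <- a[i + 1L] != b[j + 1L]; di },
                      TRUE)
    if (is_diff) {
      if (!in_run) {
        in_run <- TRUE
        pos <- c(pos, i)           # 0-based ref position of run start
        refs <- c(refs, "")
        alts <- c(alts, "")
      }
      r <- length(pos)
      if (op %in% c("M", "D")) refs[r] <- paste0(refs[r], a[i + 1L])
      if (op %in% c("M", "I")) alts[r] <- paste0(alts[r], b[j + 1L])
    } else {
      in_run <- FALSE
    }
    if (op %in% c("M", "D")) i <- i + 1L
    if (op %in% c("M", "I")) j <- j + 1L
  }
  data.frame(pos = pos, ref = refs, alt = alts, stringsAsFactors = FALSE)
}

# shift pure insertions/deletions to their leftmost equivalent position
.left_normalize <- function(variants, ref) {
  if (!nrow(variants)) return(variants)
  rb <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (r in seq_len(nrow(variants))) {
    p <- variants$pos[r]
    rr <- variants$ref[r]
    aa <- variants$alt[r]
    if (nchar(rr) && !nchar(aa)) {            # deletion of ref[p..p+d-1] (0-based)
      d <- nchar(rr)
      while (p > 0L && rb[p] == rb[p + d]) {  # rb is 1-based: rb[p] is base before run
        p <- p - 1L
        rr <- paste0(rb[p + 1L], substr(rr, 1L, d - 1L))
      }
    } else if (nchar(aa) && !nchar(rr)) {     # insertion before ref position p
      while (p > 0L && rb[p] == substr(aa, nchar(aa), nchar(aa))) {
        aa <- paste0(rb[p], substr(aa, 1L, nchar(aa) - 1L))
        p <- p - 1L
      }
    }
    variants$pos[r] <- p
    variants$ref[r] <- rr
    variants$alt[r] <- aa
  }
  variants[order(variants$pos), , drop = FALSE]
}

#' Classify an assembled path against its target
#'
#' Derives the variant set from a minimum-edit-distance global alignment of
#' the assembled sequence and the target (unit costs; ties resolved
#' deterministically and indels left-normalized to their smallest equivalent
#' position). A single contiguous difference is classified by shape as a
#' Substitution, Insertion or Deletion; two or more separated differences
#' (or one length-changing block that both consumes and adds bases) yield
#' MultiVariant.
#'
#' @param alt_sequence assembled path sequence.
#' @param target_sequence target (reference) sequence.
#' @param k anchor length; both sequences must begin and end with identical
#'   k-base anchors.
#' @return list with `path_type` and `variants` (data.frame pos/ref/alt,
#'   pos 0-based in target coordinates; insertions are placed before the
#'   target base at `pos`).
#' @export
classify_path <- function(alt_sequence, target_sequence, k = 31L) {
  if (substr(alt_sequence, 1L, k) != substr(target_sequence, 1L, k) ||
      substr(alt_sequence, nchar(alt_sequence) - k + 1L, nchar(alt_sequence)) !=
      substr(target_sequence, nchar(target_sequence) - k + 1L, nchar(target_sequence))) {
    stop("contract violation: path anchors differ from target anchors")
  }
  if (alt_sequence == target_sequence) {
    return(list(path_type = "Reference", variants = .empty_variants()))
  }
  # strip the longest common prefix/suffix first: a single local difference
  # then reduces to a tiny (often trivial) alignment problem
  n <- nchar(target_sequence); m <- nchar(alt_sequence)
  av <- strsplit(target_sequence, "", fixed = TRUE)[[1]]
  bv <- strsplit(alt_sequence, "", fixed = TRUE)[[1]]
  pmaxlen <- min(n, m)
  p <- 0L
  while (p < pmaxlen && av[p + 1L] == bv[p + 1L]) p <- p + 1L
  smaxlen <- pmaxlen - p
  s <- 0L
  while (s < smaxlen && av[n - s] == bv[m - s]) s <- s + 1L
  ref_mid <- substr(target_sequence, p + 1L, n - s)
  alt_mid <- substr(alt_sequence, p + 1L, m - s)
  if (!nchar(ref_mid) || !nchar(alt_mid)) {
    v <- data.frame(pos = p, ref = ref_mid, alt = alt_mid,
                    stringsAsFactors = FALSE)
  } else {
    ops <- .edit_align(ref_mid, alt_mid)
    v <- .alignment_variants(ref_mid, alt_mid, ops)
    v$pos <- v$pos + p
  }
  v <- .left_normalize(v, target_sequence)
  path_type <- if (nrow(v) > 1L) {
    "MultiVariant"
  } else if (nchar(v$ref[1]) && nchar(v$alt[1])) {
    if (nchar(v$ref[1]) == nchar(v$alt[1])) "Substitution" else "MultiVariant"
  } else if (nchar(v$alt[1])) "Insertion" else "Deletion"
  list(path_type = path_type, variants = v)
}

.GENETIC_CODE <- NULL

.translate_codons <- function(nt) {
  # nt length divisible by 3
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  unname(gc[codons])
}

#' Annotate a coding path call with its protein change
#'
#' For snv-category targets (built in frame with known codon coordinates),
#' translates the in-frame region of the target and of the assembled path and
#' reports the amino-acid consequence: `p.<Ref><Pos><Alt>` for missense
#' changes, `p.=` for synonymous ones, `p.<Pos>ins` / `p.<Pos>del` for
#' in-frame indels and `p.<Pos>fs` for frame-disrupting ones. Variants
#' falling outside the in-frame region are not annotated (a note is logged).
#'
#' @param call a `path_call` with a single variant.
#' @param target the snv-category `target_record` it was called against
#'   (must carry `frame_offset`, `codon_span` and `codon_offset`).
#' @return protein-change string, or `NA_character_` when not annotatable.
#' @export
annotate_protein <- function(call, target) {
  stopifnot(inherits(call, "path_call"), inherits(target, "target_record"))
  if (target$category != "snv" || is.null(target$frame_offset) ||
      is.null(target$codon_span) || is.null(target$codon_offset)) {
    stop("protein annotation requires an snv target with frame metadata")
  }
  if (call$path_type %in% c("Reference", "Absent")) return(NA_character_)
  v <- call$variants
  if (nrow(v) != 1L) {
    message("note: multi-variant path on ", target$id, "; protein annotation omitted")
    return(NA_character_)
  }
  seqc <- target$sequence
  L <- nchar(seqc)
  fo <- target$frame_offset
  ncod <- (L - fo) %/% 3L
  region_end <- fo + 3L * ncod               # 0-based exclusive
  # amino-acid number of the codon with 0-based index c (from frame_offset)
  c0 <- (target$codon_offset - fo) / 3L
  aa_num <- function(cidx) target$codon_span[1] + (cidx - c0)

  p <- v$pos[1]; rr <- v$ref[1]; aa <- v$alt[1]
  if (nchar(rr) == nchar(aa)) {              # substitution
    if (p < fo || p + nchar(rr) > region_end) {
      message("note: variant outside in-frame region of ", target$id,
              "; protein annotation omitted")
      return(NA_character_)
    }
    mutated <- paste0(substr(seqc, 1L, p), aa, substr(seqc, p + nchar(rr) + 1L, L))
    ref_aa <- .translate_codons(substr(seqc, fo + 1L, region_end))
    alt_aa <- .translate_codons(substr(mutated, fo + 1L, region_end))
    d <- which(ref_aa != alt_aa)
    if (!length(d)) return("p.=")
    paste0("p.", ref_aa[d[1]], aa_num(d[1] - 1L), alt_aa[d[1]])
  } else {                                    # indel
    if (p <= fo || p >= region_end) {
      message("note: variant outside in-frame region of ", target$id,
              "; protein annotation omitted")
      return(NA_character_)
    }
    cidx <- (p - fo) %/% 3L
    shift <- abs(nchar(aa) - nchar(rr)) %% 3L
    if (shift != 0L) {
      paste0("p.", aa_num(cidx), "fs")
    } else if (nchar(aa) > nchar(rr)) {
      paste0("p.", aa_num(cidx), "ins")
    } else {
      paste0("p.", aa_num(cidx), "del")
    }
  }
}
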