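# Test fixtures and independent oracles. Everything is generated in code;
# oracles deliberately avoid the package's own code paths.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# independent reverse complement (no stringi)
oracle_rc <- function(w) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", w), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# brute-force sliding-window dictionary counter: explicit per-window loop
oracle_count_kmers <- function(reads, k, canonical = TRUE) {
  env <- new.env(parent = emptyenv())
  for (r in reads) {
    n <- nchar(r)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      w <- substr(r, i, i + k - 1L)
      if (grepl("[^ACGT]", w)) next
      if (canonical) {
        rc <- oracle_rc(w)
        if (rc < w) w <- rc
      }
      prev <- if (is.null(env[[w]])) 0L else env[[w]]
      env[[w]] <- prev + 1L
    }
  }
  v <- unlist(as.list(env))
  if (is.null(v)) return(setNames(integer(0), character(0)))
  v[order(names(v))]
}

# direct per-window occurrence counting over the read stream
oracle_min_cov <- function(reads, target, k, canonical = TRUE) {
  allw <- unlist(lapply(reads, function(r) {
    n <- nchar(r)
    if (n < k) character(0) else substring(r, 1:(n - k + 1L), k:n)
  }))
  tws <- substring(target, 1:(nchar(target) - k + 1L), k:nchar(target))
  min(vapply(tws, function(w) {
    if (canonical) sum(allw == w | allw == oracle_rc(w)) else sum(allw == w)
  }, integer(1)))
}

# leftmost equivalent representation of a planted indel, by enumeration:
# try every position whose edit reproduces the mutant sequence
oracle_leftmost_indel <- function(target, mutant) {
  n <- nchar(target); m <- nchar(mutant)
  stopifnot(n != m)
  if (m > n) {         # insertion of length m - n
    len <- m - n
    for (p in 0:n) {
      cand <- paste0(substr(target, 1, p), substr(mutant, p + 1, p + len),
                     substr(target, p + 1, n))
      if (cand == mutant) {
        return(list(pos = p, ref = "", alt = substr(mutant, p + 1, p + len)))
      }
    }
  } else {             # deletion of length n - m
    len <- n - m
    for (p in 0:(n - len)) {
      cand <- paste0(substr(target, 1, p), substr(target, p + len + 1, n))
      if (cand == mutant) {
        return(list(pos = p, ref = substr(target, p + 1, p + len), alt = ""))
      }
    }
  }
  stop("no single indel explains the mutant")
}

toy_gene_specs <- function() {
  list(
    list(name = "FUSA", strand = "+", exon_lengths = c(120, 100, 90),
         intron_lengths = c(60, 50)),
    list(name = "FUSB", strand = "-", exon_lengths = c(110, 95, 80),
         intron_lengths = c(55, 45)),
    list(name = "VARG", strand = "+", exon_lengths = c(150, 120, 90),
         intron_lengths = c(50, 50)),
    list(name = "DELG", strand = "+", exon_lengths = rep(60, 9),
         intron_lengths = rep(45, 8)),
    list(name = "EXPR", strand = "+", exon_lengths = c(760),
         intron_lengths = numeric(0))
  )
}

# a sample carrying one fusion, one missense SNV at 50% VAF, one
# exon-skip deletion isoform and a highly expressed marker transcript
make_e2e_sample <- function(seed = 5, n_reads = 4000) {
  toy <- make_toy_genome(toy_gene_specs(), seed = seed)
  ann <- toy$annotation; gen <- toy$genome

  fus <- build_fusion_target(gen, ann,
    donor = list(gene = "FUSA", tx = "FUSA.t1", exon = 2),
    acceptor = list(gene = "FUSB", tx = "FUSB.t1", exon = 2))
  snv <- build_snv_target(gen, ann, "VARG", "VARG.t1", 40)
  del <- build_deletion_target(gen, ann, "DELG", "DELG.t1", 4, 7)
  exprtx <- spliced_transcript_sequence(gen, ann, "EXPR.t1")$sequence
  expr <- build_expression_targets(exprtx, region_end = 700, window = 70,
                                   id_prefix = "EXPR", gene = "EXPR")
  sets <- list(
    fusion = target_set("fusion", list(fus)),
    snv = target_set("snv", list(snv)),
    deletion = target_set("deletion", list(del)),
    expression = target_set("expression", expr)
  )

  txa <- spliced_transcript_sequence(gen, ann, "FUSA.t1")
  txb <- spliced_transcript_sequence(gen, ann, "FUSB.t1")
  txv <- spliced_transcript_sequence(gen, ann, "VARG.t1")
  txd <- spliced_transcript_sequence(gen, ann, "DELG.t1")
  fusion_tx <- paste0(substr(txa$sequence, 1, txa$exons$tx_end[2]),
                      substr(txb$sequence, txb$exons$tx_start[2] + 1,
                             nchar(txb$sequence)))
  ref_codon <- substr(txv$sequence, 118, 120)
  mid <- substr(ref_codon, 2, 2)
  gc <- Biostrings::GENETIC_CODE
  # pick a middle-base change that is missense and not a stop
  alt_mid <- NULL
  for (cand in setdiff(c("A", "C", "G", "T"), mid)) {
    alt_codon <- ref_codon
    substr(alt_codon, 2, 2) <- cand
    if (gc[[alt_codon]] != gc[[ref_codon]] && gc[[alt_codon]] != "*") {
      alt_mid <- cand
      break
    }
  }
  stopifnot(!is.null(alt_mid))
  substr(alt_codon, 2, 2) <- alt_mid
  var_tx <- mutate_transcript(txv$sequence,
                              list(type = "substitution", pos = 119, alt = alt_mid))
  del_tx <- mutate_transcript(txd$sequence, list(
    type = "exon_skip", start = txd$exons$tx_start[4] + 1,
    end = txd$exons$tx_end[7]))

  transcripts <- data.frame(
    id = c("fusion_tx", "varg_ref", "varg_alt", "del_iso", "expr_tx"),
    sequence = c(fusion_tx, txv$sequence, var_tx, del_tx, exprtx),
    abundance = c(1, 1, 1, 1, 3),
    stringsAsFactors = FALSE
  )
  spec <- sim_sample_spec(transcripts, read_length = 75, n_reads = n_reads,
                          seed = seed)
  sim <- simulate_reads(spec)
  list(toy = toy, sets = sets, reads = sim$reads,
       expected_protein = paste0("p.", gc[[ref_codon]], "40", gc[[alt_codon]]))
}

# one planted-variant recovery trial; returns TRUE (or a message) so callers
# can tally successes over many seeds
planted_variant_trial <- function(seed, k = 31) {
  set.seed(seed)
  L <- 110L
  target <- random_dna(L)
  type <- sample(c("sub", "ins", "del"), 1)
  if (type == "sub") {
    p <- sample((k + 1L):(L - k), 1)
    ref <- substr(target, p, p)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    mutant <- mutate_transcript(target, list(type = "substitution", pos = p, alt = alt))
    expected <- list(pos = p - 1L, ref = ref, alt = alt)
  } else if (type == "ins") {
    len <- sample(1:10, 1)
    p <- sample((k + 1L):(L - k - 1L), 1)
    ins <- random_dna(len)
    mutant <- mutate_transcript(target, list(type = "insertion", pos = p, alt = ins))
    expected <- oracle_leftmost_indel(target, mutant)
  } else {
    len <- sample(1:30, 1)
    p <- sample((k + 1L):(L - k - len + 1L), 1)
    mutant <- mutate_transcript(target, list(type = "deletion", pos = p,
                                             start = p, end = p + len - 1L))
    expected <- oracle_leftmost_indel(target, mutant)
  }
  tab <- count_kmers(c(rep(target, 8), rep(mutant, 8)), k = k)
  pcs <- walk_paths(tab, target)
  nonref <- Filter(function(x) !x$path_type %in% c("Reference", "Absent"), pcs)
  if (length(nonref) != 1L) {
    return(sprintf("seed %d: %d non-reference paths", seed, length(nonref)))
  }
  v <- nonref[[1]]$variants
  if (nrow(v) != 1L) return(sprintf("seed %d: %d variants", seed, nrow(v)))
  ok <- v$pos[1] == expected$pos && v$ref[1] == expected$ref &&
    v$alt[1] == expected$alt
  if (!ok) {
    return(sprintf("seed %d: got %d:%s>%s expected %d:%s>%s", seed,
                   v$pos[1], v$ref[1], v$alt[1],
                   expected$pos, expected$ref, expected$alt))
  }
  TRUE
}
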