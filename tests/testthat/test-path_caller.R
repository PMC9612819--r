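test_that("exact tiling yields presence with full coverage", {
  set.seed(10)
  target <- random_dna(80)
  tab <- count_kmers(rep(target, 20), k = 31)
  pr <- detect_presence(tab, target)
  expect_true(pr$present)
  expect_equal(pr$min_cov, 20L)
})

test_that("a SNP in the first or final window defeats exact matching", {
  set.seed(12)
  target <- random_dna(90)
  for (pos in c(5L, 88L)) {  # inside first window / inside last window
    ref <- substr(target, pos, pos)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    mutant <- mutate_transcript(target, list(type = "substitution",
                                             pos = pos, alt = alt))
    tab <- count_kmers(rep(mutant, 25), k = 31)
    pr <- detect_presence(tab, target)
    expect_false(pr$present)
    expect_equal(pr$min_cov, 0L)
    # no divergent path can rescue it either: the anchor itself is broken
    pcs <- walk_paths(tab, target)
    expect_equal(length(pcs), 1L)
    expect_equal(pcs[[1]]$path_type, "Absent")
    expect_equal(pcs[[1]]$min_coverage, 0L)
  }
})

test_that("random unrelated reads do not produce spurious presence", {
  set.seed(13)
  target <- random_dna(80)
  reads <- replicate(200, random_dna(75))
  tab <- count_kmers(reads, k = 31)
  pr <- detect_presence(tab, target)
  expect_false(pr$present)
  expect_equal(pr$min_cov, oracle_min_cov(reads, target, k = 31))
})

test_that("reference-only reads give a single Reference path with ratio 1", {
  set.seed(14)
  target <- random_dna(100)
  tab <- count_kmers(rep(target, 5), k = 31)
  pcs <- walk_paths(tab, target)
  expect_equal(length(pcs), 1L)
  expect_equal(pcs[[1]]$path_type, "Reference")
  expect_equal(pcs[[1]]$alt_sequence, target)
  expect_equal(pcs[[1]]$ratio, 0.5)  # alt path IS the reference path here
  expect_equal(pcs[[1]]$min_coverage, 5L)
  expect_gte(pcs[[1]]$min_coverage, 1L)
})

test_that("a 50:50 substitution mixture yields both paths with balanced ratio", {
  set.seed(15)
  target <- random_dna(120)
  p <- 60L
  ref <- substr(target, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mutant <- mutate_transcript(target, list(type = "substitution", pos = p, alt = alt))
  spec <- sim_sample_spec(
    data.frame(id = c("ref", "alt"), sequence = c(target, mutant),
               abundance = c(1, 1), stringsAsFactors = FALSE),
    read_length = 75, n_reads = 80, seed = 99)
  tab <- count_kmers(simulate_reads(spec)$reads, k = 31)
  pcs <- walk_paths(tab, target)
  types <- sort(vapply(pcs, function(x) x$path_type, character(1)))
  expect_equal(types, c("Reference", "Substitution"))
  sub <- Filter(function(x) x$path_type == "Substitution", pcs)[[1]]
  expect_equal(sub$variants$pos, p - 1L)
  expect_equal(sub$variants$ref, ref)
  expect_equal(sub$variants$alt, alt)
  expect_gte(sub$ratio, 0.35)
  expect_lte(sub$ratio, 0.65)
})

test_that("a deletion-only sample yields ratio 1 with broken reference", {
  set.seed(16)
  target <- random_dna(120)
  mutant <- mutate_transcript(target, list(type = "deletion", start = 60, end = 62))
  tab <- count_kmers(rep(mutant, 12), k = 31)
  pcs <- walk_paths(tab, target)
  dels <- Filter(function(x) x$path_type == "Deletion", pcs)
  expect_equal(length(dels), 1L)
  expect_equal(dels[[1]]$ref_min_coverage, 0L)
  expect_equal(dels[[1]]$ratio, 1.0)
  expect_equal(nchar(dels[[1]]$variants$ref), 3L)
})

test_that("assembled paths are sound and keep their anchors", {
  set.seed(17)
  for (i in 1:5) {
    target <- random_dna(110)
    p <- sample(40:70, 1)
    edit <- sample(c("sub", "ins", "del"), 1)
    mutant <- switch(edit,
      sub = mutate_transcript(target, list(type = "substitution", pos = p,
        alt = setdiff(c("A", "C", "G", "T"), substr(target, p, p))[1])),
      ins = mutate_transcript(target, list(type = "insertion", pos = p,
                                           alt = random_dna(4))),
      del = mutate_transcript(target, list(type = "deletion", start = p,
                                           end = p + 5)))
    tab <- count_kmers(c(rep(target, 6), rep(mutant, 6)), k = 31)
    pcs <- walk_paths(tab, target, min_count = 2L)
    for (pc in pcs) {
      expect_false(pc$path_type == "Absent")
      # soundness: every window of the spelled path clears min_count
      w <- substring(pc$alt_sequence, 1:(nchar(pc$alt_sequence) - 30),
                     31:nchar(pc$alt_sequence))
      expect_true(all(kmer_lookup(tab, w) >= 2L))
      # anchor invariant
      expect_equal(substr(pc$alt_sequence, 1, 31), substr(target, 1, 31))
      expect_equal(substr(pc$alt_sequence, nchar(pc$alt_sequence) - 30,
                          nchar(pc$alt_sequence)),
                   substr(target, 80, 110))
    }
  }
})

test_that("classification agrees with exhaustive alignment oracles", {
  # single mismatch
  set.seed(18)
  target <- random_dna(100)
  alt <- mutate_transcript(target, list(type = "substitution", pos = 36,
    alt = setdiff(c("A", "C", "G", "T"), substr(target, 36, 36))[1]))
  cl <- classify_path(alt, target, k = 31)
  expect_equal(cl$path_type, "Substitution")
  expect_equal(cl$variants$pos, 35L)

  # insertion in a homopolymer run lands at the leftmost equivalent position
  t2 <- paste0(random_dna(40), "AAAAAA", random_dna(40))
  a2 <- paste0(substr(t2, 1, 43), "A", substr(t2, 44, 86))
  cl2 <- classify_path(a2, t2, k = 31)
  expect_equal(cl2$path_type, "Insertion")
  expect_equal(cl2$variants$pos, oracle_leftmost_indel(t2, a2)$pos)
  expect_equal(cl2$variants$alt, "A")

  # deletion in a repeat likewise
  a3 <- paste0(substr(t2, 1, 41), substr(t2, 44, 86))
  cl3 <- classify_path(a3, t2, k = 31)
  expect_equal(cl3$path_type, "Deletion")
  expect_equal(cl3$variants$pos, oracle_leftmost_indel(t2, a3)$pos)

  # identity and separated differences
  expect_equal(classify_path(target, target, k = 31)$path_type, "Reference")
  a4 <- mutate_transcript(alt, list(type = "substitution", pos = 60,
    alt = setdiff(c("A", "C", "G", "T"), substr(target, 60, 60))[1]))
  expect_equal(classify_path(a4, target, k = 31)$path_type, "MultiVariant")

  # anchor contract
  expect_error(classify_path(paste0("A", substr(target, 2, 100)), target,
                             k = 31), "anchor")
})

test_that("protein annotation reproduces known missense notations", {
  # build a target whose codon 80 is CCT (P) and codon 159 is AAT (N)
  set.seed(19)
  flank_codons <- function(n) paste(replicate(n, sample(c("GCT", "GGA", "TCA",
    "CTG", "ACC"), 1)), collapse = "")
  seq80 <- paste0(flank_codons(11), "CCT", flank_codons(11))
  t80 <- target_record("PAX5like_p80", "snv", seq80, genes = "PAX5like",
                       codon_span = c(80, 80), frame_offset = 0,
                       codon_offset = 33)
  alt80 <- paste0(substr(seq80, 1, 34), "G", substr(seq80, 36, 69))
  call80 <- walk_paths(count_kmers(c(rep(seq80, 6), rep(alt80, 6)), k = 31),
                       t80)
  sub80 <- Filter(function(x) x$path_type == "Substitution", call80)[[1]]
  expect_equal(annotate_protein(sub80, t80), "p.P80R")

  seq159 <- paste0(flank_codons(11), "AAT", flank_codons(11))
  t159 <- target_record("IKZF1like_p159", "snv", seq159, genes = "IKZF1like",
                        codon_span = c(159, 159), frame_offset = 0,
                        codon_offset = 33)
  alt159 <- paste0(substr(seq159, 1, 33), "T", substr(seq159, 35, 69))
  call159 <- walk_paths(count_kmers(c(rep(seq159, 6), rep(alt159, 6)), k = 31),
                        t159)
  sub159 <- Filter(function(x) x$path_type == "Substitution", call159)[[1]]
  expect_equal(annotate_protein(sub159, t159), "p.N159Y")

  # synonymous change: CTG -> CTA (both Leu) at the target codon
  seqsyn <- paste0(flank_codons(11), "CTG", flank_codons(11))
  tsyn <- target_record("syn_p10", "snv", seqsyn, codon_span = c(10, 10),
                        frame_offset = 0, codon_offset = 33)
  altsyn <- paste0(substr(seqsyn, 1, 35), "A", substr(seqsyn, 37, 69))
  pc <- structure(list(target_id = "syn_p10", path_type = "Substitution",
                       alt_sequence = altsyn,
                       variants = data.frame(pos = 35L, ref = "G", alt = "A",
                                             stringsAsFactors = FALSE),
                       min_coverage = 10L, ref_min_coverage = 10L,
                       ratio = 0.5), class = "path_call")
  expect_equal(annotate_protein(pc, tsyn), "p.=")

  # frame-disrupting insertion
  pcfs <- structure(list(target_id = "syn_p10", path_type = "Insertion",
                         alt_sequence = paste0(substr(seqsyn, 1, 35), "TG",
                                               substr(seqsyn, 36, 69)),
                         variants = data.frame(pos = 35L, ref = "",
                                               alt = "TG",
                                               stringsAsFactors = FALSE),
                         min_coverage = 10L, ref_min_coverage = 10L,
                         ratio = 0.5), class = "path_call")
  expect_equal(annotate_protein(pcfs, tsyn), "p.10fs")

  # in-frame insertion
  pcins <- pcfs
  pcins$variants$alt <- "TGA"
  expect_equal(annotate_protein(pcins, tsyn), "p.10ins")
})
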