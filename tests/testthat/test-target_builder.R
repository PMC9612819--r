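toy <- make_toy_genome(toy_gene_specs(), seed = 11)

test_that("spliced extraction matches a per-base oracle on both strands", {
  chrom_seq <- as.character(toy$genome[[1]])
  for (tx in c("FUSA.t1", "FUSB.t1")) {
    sp <- spliced_transcript_sequence(toy$genome, toy$annotation, tx)
    # independent per-base extraction through the coordinate map
    oracle <- vapply(seq_len(nrow(sp$map)), function(i) {
      b <- substr(chrom_seq, sp$map$pos[i], sp$map$pos[i])
      if (sp$strand == "-") chartr("ACGT", "TGCA", b) else b
    }, character(1))
    expect_equal(paste(oracle, collapse = ""), sp$sequence)
    expect_equal(nrow(sp$map), nchar(sp$sequence))
  }
  # strand symmetry: a minus-strand gene's transcript is the reverse
  # complement of its plus-strand reading
  spb <- spliced_transcript_sequence(toy$genome, toy$annotation, "FUSB.t1")
  plus_read <- paste(vapply(sort(spb$map$pos), function(p) {
    substr(chrom_seq, p, p)
  }, character(1)), collapse = "")
  expect_equal(spb$sequence, oracle_rc(plus_read))
  expect_error(spliced_transcript_sequence(toy$genome, toy$annotation,
                                           "NOPE.t1"), "no exon features")
})

test_that("fusion targets join 31-base exon ends at a 62-base junction", {
  fus <- build_fusion_target(toy$genome, toy$annotation,
    donor = list(gene = "FUSA", tx = "FUSA.t1", exon = 2),
    acceptor = list(gene = "FUSB", tx = "FUSB.t1", exon = 2))
  expect_equal(nchar(fus$sequence), 62L)
  expect_equal(fus$breakpoint_offset, 31L)
  expect_equal(fus$id, "FUSA-FUSB_e2e2")
  txa <- spliced_transcript_sequence(toy$genome, toy$annotation, "FUSA.t1")
  txb <- spliced_transcript_sequence(toy$genome, toy$annotation, "FUSB.t1")
  # each half occurs verbatim in its spliced parent transcript
  expect_true(grepl(substr(fus$sequence, 1, 31), txa$sequence, fixed = TRUE))
  expect_true(grepl(substr(fus$sequence, 32, 62), txb$sequence, fixed = TRUE))
  # manual concatenation oracle
  expect_equal(substr(fus$sequence, 1, 31),
               substr(txa$sequence, txa$exons$tx_end[2] - 30,
                      txa$exons$tx_end[2]))
  expect_equal(substr(fus$sequence, 32, 62),
               substr(txb$sequence, txb$exons$tx_start[2] + 1,
                      txb$exons$tx_start[2] + 31))
  # the junction itself is novel: absent from both parents
  expect_false(grepl(fus$sequence, txa$sequence, fixed = TRUE))
  expect_false(grepl(fus$sequence, txb$sequence, fixed = TRUE))
  # the reciprocal invocation gives a distinct second target
  rec <- build_fusion_target(toy$genome, toy$annotation,
    donor = list(gene = "FUSB", tx = "FUSB.t1", exon = 2),
    acceptor = list(gene = "FUSA", tx = "FUSA.t1", exon = 2))
  expect_equal(rec$id, "FUSB-FUSA_e2e2")
  expect_false(rec$sequence == fus$sequence)
  expect_error(build_fusion_target(toy$genome, toy$annotation,
    donor = list(gene = "FUSA", tx = "FUSA.t1", exon = 9),
    acceptor = list(gene = "FUSB", tx = "FUSB.t1", exon = 2)), "exon")
})

test_that("snv targets are in frame with 33-base flanks", {
  snv <- build_snv_target(toy$genome, toy$annotation, "VARG", "VARG.t1", 40)
  expect_equal(nchar(snv$sequence), 69L)   # 33 + 3 + 33
  expect_equal(snv$codon_span, c(40L, 40L))
  expect_equal(snv$frame_offset, 0L)
  expect_equal(snv$codon_offset, 33L)
  cds <- spliced_transcript_sequence(toy$genome, toy$annotation, "VARG.t1",
                                     feature = "CDS")
  expect_equal(substr(snv$sequence, 34, 36), substr(cds$sequence, 118, 120))
  # translating from the frame offset reproduces the annotated residue
  gc <- Biostrings::GENETIC_CODE
  expect_equal(gc[[substr(snv$sequence, 34, 36)]],
               gc[[substr(cds$sequence, 118, 120)]])

  two <- build_snv_target(toy$genome, toy$annotation, "VARG", "VARG.t1",
                          40, 41)
  expect_equal(nchar(two$sequence), 72L)   # 33 + 6 + 33

  # a codon 11 bases from the exon-1/exon-2 boundary: flank crosses the
  # junction, so the target must match spliced (not genomic) extraction
  near <- build_snv_target(toy$genome, toy$annotation, "VARG", "VARG.t1", 54)
  # codon 54 occupies CDS offsets 159-162; exon 1 ends at 150
  expect_true(grepl(near$sequence, cds$sequence, fixed = TRUE))
  chrom_seq <- as.character(toy$genome[[1]])
  genomic_span <- substr(chrom_seq, min(near$coord_map$pos),
                         max(near$coord_map$pos))
  expect_gt(nchar(genomic_span), nchar(near$sequence))  # intron was skipped

  expect_error(build_snv_target(toy$genome, toy$annotation, "VARG",
                                "VARG.t1", 2), "too close")
})

test_that("deletion junction targets join the flanking exons", {
  del <- build_deletion_target(toy$genome, toy$annotation, "DELG", "DELG.t1",
                               4, 7)
  expect_equal(nchar(del$sequence), 62L)
  expect_equal(del$id, "DELG_del_e4-7")
  txd <- spliced_transcript_sequence(toy$genome, toy$annotation, "DELG.t1")
  expect_equal(del$sequence,
               paste0(substr(txd$sequence, txd$exons$tx_end[3] - 30,
                             txd$exons$tx_end[3]),
                      substr(txd$sequence, txd$exons$tx_start[8] + 1,
                             txd$exons$tx_start[8] + 31)))
  del2 <- build_deletion_target(toy$genome, toy$annotation, "DELG", "DELG.t1",
                                2, 7)
  expect_equal(substr(del2$sequence, 1, 31),
               substr(txd$sequence, txd$exons$tx_end[1] - 30,
                      txd$exons$tx_end[1]))
  # ranges touching terminal exons leave no junction to observe
  expect_error(build_deletion_target(toy$genome, toy$annotation, "DELG",
                                     "DELG.t1", 1, 3), "first or last")
  expect_error(build_deletion_target(toy$genome, toy$annotation, "DELG",
                                     "DELG.t1", 8, 9), "first or last")
})

test_that("expression windows tile kept intervals with exact widths", {
  set.seed(40)
  tx <- random_dna(760)
  # no exclusions: floor(700/70) = 10 windows
  w0 <- build_expression_targets(tx, region_end = 700, window = 70,
                                 exclusions = list())
  expect_equal(length(w0), 10L)
  # excluding 141-210 leaves [1,140] and [211,700]: 2 + 7 = 9 windows
  w1 <- build_expression_targets(tx, region_end = 700, window = 70)
  expect_equal(length(w1), 9L)
  expect_true(all(vapply(w1, function(r) nchar(r$sequence), integer(1)) == 70L))
  # windows avoid the excluded interval and come from the source
  for (r in w1) expect_true(grepl(r$sequence, tx, fixed = TRUE))
  expect_equal(w1[[3]]$sequence, substr(tx, 211, 280))
  expect_warning(w2 <- build_expression_targets(random_dna(60),
                                                region_end = 60, window = 70),
                 "shorter")
  expect_equal(length(w2), 0L)
})

test_that("IG-rearrangement targets pair a 50-base prefix with each allele", {
  set.seed(41)
  partner <- random_dna(300)
  alleles <- c(IGHJ1 = random_dna(40), IGHJ2 = random_dna(25),
               IGKD3 = random_dna(33))
  igs <- build_ig_targets(partner, 200, alleles, partner_name = "CRLF2")
  expect_equal(length(igs), 3L)
  prefix <- substr(partner, 150, 199)
  for (i in seq_along(igs)) {
    expect_equal(substr(igs[[i]]$sequence, 1, 50), prefix)
    expect_equal(nchar(igs[[i]]$sequence), 50L + nchar(alleles[[i]]))
  }
  expect_equal(igs[[1]]$id, "CRLF2__IGHJ1")
  expect_error(build_ig_targets(partner, 200, character(0)), "empty")
  expect_error(build_ig_targets(partner, 30, alleles), "too close")
})

test_that("population-SNP alternates obey the frequency threshold", {
  snv <- build_snv_target(toy$genome, toy$annotation, "VARG", "VARG.t1", 40)
  gp <- snv$coord_map[10, ]   # a genomic position inside the target
  ref <- substr(snv$sequence, 10, 10)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  mk <- function(af, pos = gp$pos) {
    data.frame(chrom = gp$chrom, pos = pos, ref = ref, alt = alt, af = af,
               stringsAsFactors = FALSE)
  }
  out <- add_snp_alternates(snv, mk(0.02))
  expect_equal(length(out), 2L)
  expect_equal(substr(out[[2]]$sequence, 10, 10), alt)
  expect_match(out[[2]]$id, "SNP")
  # at or below threshold: original only
  expect_equal(length(add_snp_alternates(snv, mk(0.005))), 1L)
  expect_equal(length(add_snp_alternates(snv, mk(0.01))), 1L)
  # outside the target span: original only
  expect_equal(length(add_snp_alternates(snv, mk(0.5, pos = 1L))), 1L)
})

test_that("catalogs build deterministically and revalidate", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  spec_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "FUSA\tFUSA.t1\t2\tFUSB\tFUSB.t1\t2",
    "FUSB\tFUSB.t1\t2\tFUSA\tFUSA.t1\t2",
    "VARG\tVARG.t1\t40\t40",
    "DELG\tDELG.t1\tdel\t4\t7",
    "NOGENE\tNOPE.t1\t3\t3"
  ), spec_path)
  res1 <- build_catalog(toy$genome, toy$annotation, spec_path, dir1)
  res2 <- build_catalog(toy$genome, toy$annotation, spec_path, dir2)
  expect_equal(length(res1$errors), 1L)          # unresolvable row reported
  expect_match(res1$errors, "NOPE.t1")
  expect_equal(sort(basename(res1$files)),
               c("deletion.fa", "fusion.fa", "snv.fa"))
  expect_equal(length(res1$sets$fusion), 2L)
  for (f in basename(res1$files)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # every written record passes validation on re-read
  for (cat in names(res1$sets)) {
    back <- read_target_fasta(file.path(dir1, paste0(cat, ".fa")), cat)
    expect_equal(length(back), length(res1$sets[[cat]]))
  }
})
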