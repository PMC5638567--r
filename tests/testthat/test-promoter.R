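test_that("alignment handles identity, substitution and deletion correctly", {
  id <- align_pair("ACGT", "ACGT")
  expect_equal(id$score, 4)
  expect_equal(id$aligned_a, "ACGT")
  expect_equal(id$aligned_b, "ACGT")
  del <- align_pair("ACGTA", "ACTA")
  expect_equal(del$score, 2) # 4 matches - 1 gap
  expect_equal(nchar(del$aligned_a), 5)
  snp <- align_pair("ACGT", "ACTT")
  expect_equal(snp$score, 2) # 3 matches - 1 mismatch
  expect_false(grepl("-", snp$aligned_a))
  expect_error(align_pair("", "ACGT"), class = "taqase_invalid_sequence")
  expect_error(align_pair("ACGT", "ACXT"),
               class = "taqase_invalid_sequence")
})

test_that("alignment score equals the exhaustive optimum on short sequences", {
  withr::with_seed(60, {
    for (i in 1:40) {
      a <- random_dna(sample(1:8, 1))
      b <- random_dna(sample(1:8, 1))
      aln <- align_pair(a, b)
      expect_equal(aln$score, nw_oracle_score(a, b),
                   info = paste(a, b))
      # the reported alignment must itself realise the reported score
      av <- strsplit(aln$aligned_a, "")[[1]]
      bv <- strsplit(aln$aligned_b, "")[[1]]
      col_score <- ifelse(av == "-" | bv == "-", -2,
                          ifelse(av == bv, 1, -1))
      expect_equal(sum(col_score), aln$score)
    }
  })
})

test_that("alignment score matches an independent aligner on longer pairs", {
  withr::with_seed(61, {
    for (i in 1:5) {
      a <- random_dna(120)
      b <- paste(strsplit(a, "")[[1]][-(10:12)], collapse = "")
      mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1,
                                                      mismatch = -1)
      ref <- Biostrings::pairwiseAlignment(a, b, substitutionMatrix = mat,
                                           gapOpening = 0, gapExtension = 2,
                                           type = "global",
                                           scoreOnly = TRUE)
      expect_equal(align_pair(a, b)$score, ref)
    }
  })
})

test_that("variant calls recover planted differences", {
  expect_equal(nrow(find_variants(align_pair("ACGTACGT", "ACGTACGT"))), 0)
  snp <- find_variants(align_pair("ACGT", "ACTT"))
  expect_equal(snp$position, 3)
  expect_equal(snp$kind, "SNP")
  expect_equal(snp$allele_a, "G")
  expect_equal(snp$allele_b, "T")
  pair <- simulate_promoter_pair(seed = 7)
  v <- find_variants(align_pair(pair$seq_a, pair$seq_b))
  expect_equal(nrow(v), 2)
  expect_equal(v$position[v$kind == "SNP"], 77)
  expect_equal(v$position[v$kind == "DELETION"], 231)
  expect_equal(v$allele_b[v$kind == "DELETION"], "")
  # adjacent gap columns merge into one event
  multi <- find_variants(align_pair("AAACGTTT", "AAATTT"))
  expect_equal(nrow(multi), 1)
  expect_equal(multi$kind, "DELETION")
  expect_equal(multi$allele_a, "CG")
  expect_equal(multi$position, 4)
})

test_that("variant counts are symmetric under swapping the sequences", {
  withr::with_seed(62, {
    for (i in 1:10) {
      pair <- simulate_promoter_pair(length = 300, snp_pos = 40,
                                     indel_pos = 150, island_span = NULL,
                                     seed = 100 + i)
      v_ab <- find_variants(align_pair(pair$seq_a, pair$seq_b))
      v_ba <- find_variants(align_pair(pair$seq_b, pair$seq_a))
      expect_equal(sum(v_ab$kind == "SNP"), sum(v_ba$kind == "SNP"))
      expect_equal(sum(v_ab$kind %in% c("INSERTION", "DELETION")),
                   sum(v_ba$kind %in% c("INSERTION", "DELETION")))
      # the deletion becomes an insertion anchored one base 5' of the plant
      ins <- v_ba[v_ba$kind == "INSERTION", ]
      expect_equal(ins$position, 149)
    }
  })
})

test_that("CpG window statistics have the right closed forms", {
  cg <- strrep("CG", 300)
  expect_equal(gc_fraction(cg), 1)
  expect_equal(obs_exp_cpg(cg), 300 * 600 / (300 * 300)) # = 2
  expect_equal(gc_fraction("ATAT"), 0)
  expect_equal(obs_exp_cpg("ATAT"), 0)
  # N bases leave both numerator and denominator
  expect_equal(gc_fraction("CGNN"), 1)
  islands <- predict_cpg_islands(cg)
  expect_equal(nrow(islands), 1)
  expect_equal(islands$start, 1)
  expect_equal(islands$end, 600)
  expect_equal(islands$gc_fraction, 1)
  expect_equal(islands$obs_exp_cpg, 2)
  expect_equal(nrow(predict_cpg_islands(strrep("A", 600))), 0)
  expect_warning(out <- predict_cpg_islands("ACGT"), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("island calls agree with the naive window oracle", {
  withr::with_seed(63, {
    seqs <- list(
      simulate_promoter_pair(seed = 7)$seq_a,
      simulate_promoter_pair(length = 1000, snp_pos = 100, indel_pos = 500,
                             island_span = c(300, 650), seed = 64)$seq_a,
      random_dna(800),
      paste0(random_dna(300), strrep("CG", 150), random_dna(300)),
      random_dna(600, alphabet = c("A", "C", "G", "T", "N"))
    )
  })
  for (s in seqs) {
    got <- predict_cpg_islands(s)
    want <- cpg_oracle(s)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$gc_fraction, want$gc_fraction, tolerance = 1e-12)
      expect_equal(got$obs_exp_cpg, want$obs_exp_cpg, tolerance = 1e-12)
    }
  }
})

test_that("island calls on a planted GC-rich block overlap the plant", {
  pair <- simulate_promoter_pair(length = 1000, snp_pos = 50,
                                 indel_pos = 800,
                                 island_span = c(200, 520), seed = 12)
  islands <- predict_cpg_islands(pair$seq_a)
  expect_equal(nrow(islands), 1)
  expect_lt(islands$start, 520)
  expect_gt(islands$end, 200)
  expect_gt(islands$length, 200)
  expect_gt(islands$gc_fraction, 0.5)
  expect_gt(islands$obs_exp_cpg, 0.6)
  # no island without the plant
  bare <- simulate_promoter_pair(length = 1000, snp_pos = 50,
                                 indel_pos = 800, island_span = NULL,
                                 seed = 12)
  expect_equal(nrow(predict_cpg_islands(bare$seq_a)), 0)
})

test_that("GC content is strand symmetric", {
  withr::with_seed(65, s <- random_dna(400))
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]),
                                     collapse = ""))
  expect_equal(gc_fraction(s), gc_fraction(rc), tolerance = 1e-12)
  # a CG repeat is its own reverse complement: identical island calls
  cg <- strrep("CG", 300)
  rc_cg <- chartr("ACGT", "TGCA", paste(rev(strsplit(cg, "")[[1]]),
                                        collapse = ""))
  expect_equal(predict_cpg_islands(cg), predict_cpg_islands(rc_cg))
})

test_that("FASTA round-trips through Biostrings", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  pair <- simulate_promoter_pair(seed = 3)
  tbl <- tibble::tibble(id = c("alleleA", "alleleB"),
                        sequence = c(pair$seq_a, pair$seq_b))
  write_promoter_fasta(tbl, tmp)
  back <- read_promoter_fasta(tmp)
  expect_equal(back, tbl)
})
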