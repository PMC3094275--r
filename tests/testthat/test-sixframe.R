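test_that("six-frame translation follows the standard code and frame rules", {
  fr <- six_frame_translate("ATGAAA")
  expect_equal(fr[["F1"]], "MK")
  # reverse complement of TTTCAT is ATGAAA
  expect_equal(six_frame_translate("TTTCAT")[["R1"]], "MK")
  # trailing partial codons are dropped
  fr4 <- six_frame_translate("ATGA")
  expect_equal(fr4[["F1"]], "M")
  expect_equal(nchar(fr4[["F2"]]), 1L)  # TGA -> *
  expect_equal(fr4[["F3"]], "")
  # too short for any codon: all empty, no error
  expect_equal(unname(six_frame_translate("AT")), rep("", 6L))
  # N-containing codons translate to X
  expect_equal(six_frame_translate("ATGANA")[["F1"]], "MX")
  # agrees with the hand-rolled oracle on random sequences
  set.seed(21)
  for (rep in 1:25) {
    s <- random_dna(sample(10:200, 1L))
    expect_equal(six_frame_translate(s), unlist(oracle_six_frame(s)))
  }
})

test_that("forward and reverse hits carry the forced local coordinates", {
  h <- find_peptide_matches("MK", "t", "ATGAAA", "p1", min_length = 2L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$frame, "F1")
  expect_equal(h$aa_offset, 0L)
  expect_equal(c(h$local_start, h$local_end), c(1L, 6L))

  # N = 6, R1: start = N-(f+3a+3L)+1 = 1, end = N-f-3a = 6
  hr <- find_peptide_matches("MK", "t", "TTTCAT", "p1", min_length = 2L)
  expect_equal(hr$frame, "R1")
  expect_equal(c(hr$local_start, hr$local_end), c(1L, 6L))
  # re-translating the reverse-complemented slice reproduces the peptide
  slice <- substr("TTTCAT", hr$local_start, hr$local_end)
  expect_equal(oracle_translate(oracle_revcomp(slice)), "MK")
})

test_that("I/L equivalence is honored during matching", {
  # ATGCTG encodes ML
  expect_equal(nrow(find_peptide_matches("MI", "t", "ATGCTG",
                                         il_equivalent = TRUE,
                                         min_length = 2L)), 1L)
  expect_equal(nrow(find_peptide_matches("MI", "t", "ATGCTG",
                                         il_equivalent = FALSE,
                                         min_length = 2L)), 0L)
})

test_that("invalid peptides error and short peptides return no hits", {
  expect_error(find_peptide_matches("MK2", "t", "ATGAAA"), "non-amino-acid")
  expect_equal(nrow(find_peptide_matches("MK", "t", "ATGAAA",
                                         min_length = 6L)), 0L)
})

test_that("hit sets equal the all-offsets brute-force oracle on random targets", {
  set.seed(31)
  for (rep in 1:15) {
    target <- random_dna(sample(300:900, 1L))
    frames <- six_frame_translate(target)
    # peptides cut from real frames (guaranteed hits) plus random decoys
    peps <- character()
    for (k in 1:4) {
      fr <- sample(names(frames), 1L)
      aa <- gsub("\\*", "", frames[[fr]])
      if (nchar(aa) >= 8L) {
        a0 <- sample(nchar(aa) - 7L, 1L)
        peps <- c(peps, substr(frames[[fr]], a0, a0 + 6L))
      }
    }
    peps <- c(peps[!grepl("[*X]", peps)],
              paste(sample(c("A", "G", "V", "W", "K"), 7, TRUE),
                    collapse = ""))
    for (pep in peps) {
      got <- find_peptide_matches(pep, "t", target, min_length = 2L)
      got <- got[order(got$frame, got$aa_offset),
                 c("frame", "aa_offset", "local_start", "local_end")]
      rownames(got) <- NULL
      want <- oracle_find_matches(pep, target)
      rownames(want) <- NULL
      expect_identical(got, want)
    }
  }
})

test_that("every reported hit spans 3x the peptide length and re-translates to it", {
  set.seed(32)
  n_checked <- 0L
  while (n_checked < 200L) {
    target <- random_dna(sample(200:600, 1L))
    frames <- six_frame_translate(target)
    fr <- sample(FRAME_NAMES <- c("F1","F2","F3","R1","R2","R3"), 1L)
    aa <- frames[[fr]]
    if (nchar(aa) < 9L) next
    a0 <- sample(nchar(aa) - 8L, 1L)
    pep <- substr(aa, a0, a0 + 7L)
    if (grepl("[*X]", pep)) next
    hits <- find_peptide_matches(pep, "t", target, min_length = 2L)
    expect_gte(nrow(hits), 1L)
    for (i in seq_len(nrow(hits))) {
      expect_equal(hits$local_end[i] - hits$local_start[i] + 1L,
                   3L * nchar(pep))
      slice <- substr(target, hits$local_start[i], hits$local_end[i])
      if (startsWith(hits$frame[i], "R")) slice <- oracle_revcomp(slice)
      expect_equal(chartr("I", "L", oracle_translate(slice)),
                   chartr("I", "L", pep))
      n_checked <- n_checked + 1L
    }
  }
})

test_that("lifting to chromosome coordinates is offset arithmetic and invertible", {
  g <- make_gene("g1", "chr1", 101L, 400L, "+",
                 data.frame(start = 101L, end = 400L))
  h <- data.frame(peptide_id = "p", target_id = "g1", frame = "F1",
                  aa_offset = 0L, local_start = 1L, local_end = 6L,
                  stringsAsFactors = FALSE)
  lifted <- lift_to_chromosome(h, g)
  expect_equal(c(lifted$chrom_start, lifted$chrom_end), c(101L, 106L))
  expect_equal(lifted$strand, "+")

  h2 <- h; h2$local_start <- 295L; h2$local_end <- 300L; h2$frame <- "R2"
  l2 <- lift_to_chromosome(h2, g)
  expect_equal(c(l2$chrom_start, l2$chrom_end), c(395L, 400L))
  expect_equal(l2$strand, "-")
  # invertible: local = chrom - gene.start + 1
  expect_equal(l2$chrom_start - g$start + 1L, h2$local_start)

  gneg <- make_gene("g1", "chr1", 101L, 400L, "-",
                    data.frame(start = 101L, end = 400L))
  expect_equal(lift_to_chromosome(h, gneg)$strand, "-")
  expect_equal(lift_to_chromosome(h2, gneg)$strand, "+")

  hbad <- h; hbad$local_end <- 999L
  expect_error(lift_to_chromosome(hbad, g), "outside gene span")
  hwrong <- h; hwrong$target_id <- "other"
  expect_error(lift_to_chromosome(hwrong, g), "does not match gene")
})

test_that("translating lifted chromosome slices reproduces the peptide", {
  set.seed(33)
  chrom <- random_dna(3000)
  checked <- 0L
  while (checked < 100L) {
    gs <- sample(1:2000, 1L)
    ge <- gs + sample(200:600, 1L)
    ge <- min(ge, nchar(chrom))
    g <- make_gene("g", "chrT", gs, ge, sample(c("+", "-"), 1L),
                   data.frame(start = gs, end = ge))
    target <- substr(chrom, gs, ge)
    frames <- six_frame_translate(target)
    fr <- sample(c("F1", "F2", "F3", "R1", "R2", "R3"), 1L)
    aa <- frames[[fr]]
    if (nchar(aa) < 9L) next
    a0 <- sample(nchar(aa) - 8L, 1L)
    pep <- substr(aa, a0, a0 + 7L)
    if (grepl("[*X]", pep)) next
    hits <- lift_to_chromosome(
      find_peptide_matches(pep, "g", target, min_length = 2L), g)
    for (i in seq_len(nrow(hits))) {
      slice <- substr(chrom, hits$chrom_start[i], hits$chrom_end[i])
      if (startsWith(hits$frame[i], "R")) slice <- oracle_revcomp(slice)
      expect_equal(chartr("I", "L", oracle_translate(slice)),
                   chartr("I", "L", pep))
    }
    checked <- checked + nrow(hits)
  }
})
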