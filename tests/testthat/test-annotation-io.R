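test_that("parse_gff3 reads minimal files and preserves coordinates and links", {
  f <- parse_gff3(c("chr1\tsrc\tgene\t101\t400\t.\t+\t.\tID=g1",
                    "chr1\tsrc\tmRNA\t101\t400\t.\t+\t.\tID=g1.1;Parent=g1",
                    "chr1\tsrc\texon\t101\t200\t.\t+\t.\tParent=g1.1"))
  expect_equal(nrow(f), 3L)
  expect_equal(f$start, c(101L, 101L, 101L))
  expect_equal(f$end, c(400L, 400L, 200L))
  expect_equal(f$feature_id, c("g1", "g1.1", NA))
  expect_equal(f$parent, c(NA, "g1", "g1.1"))

  empty <- withr::local_tempfile(lines = character())
  expect_equal(nrow(parse_gff3(empty)), 0L)
})

test_that("parse_gff3 rejects malformed lines with the line number", {
  expect_error(parse_gff3(c("chr1\tsrc\tgene\t200\t100\t.\t+\t.\tID=g1")),
               "line 1.*start > end")
  expect_error(
    parse_gff3(c("chr1\tsrc\tgene\t1\t10\t.\t+\t.\tID=a",
                 "chr1\tsrc\tgene\t1\t10\t.\t+")),
    "line 2.*9 tab-separated")
  expect_error(parse_gff3(c("chr1\tsrc\tgene\tx\t10\t.\t+\t.\tID=a")),
               "non-integer")
})

test_that("GFF3 write/parse round trip is lossless on all nine columns", {
  lines <- fixture_gff3_lines()
  f <- parse_gff3(lines)
  out <- write_gff3(f)
  expect_identical(out, lines)   # byte-identical, directive included
  f2 <- parse_gff3(out)
  expect_identical(f, f2)

  # peptide feature with parent:peptideID notation survives verbatim
  pep <- "chrX\tpgmap:P\tpeptide\t501\t530\t.\t+\t.\tID=LOC_Os06g01230.1:P62531;Parent=LOC_Os06g01230.1"
  rt <- write_gff3(parse_gff3(c("##gff-version 3", pep)))
  expect_identical(rt[2L], pep)
})

test_that("missing score serializes as '.' and missing seqid errors", {
  f <- parse_gff3("chr1\tsrc\tgene\t1\t9\t.\t+\t.\tID=g")
  expect_match(write_gff3(f)[2L], "\t\\.\t\\+")
  f$seqid <- ""
  expect_error(write_gff3(f), "seqid")
})

test_that("gene models derive sorted exons and intron complements", {
  models <- assemble_gene_models(parse_gff3(fixture_gff3_lines()))
  expect_named(models, c("gA", "gB"))
  gA <- models$gA
  expect_equal(gA$exon_union, data.frame(start = c(101L, 301L),
                                         end = c(200L, 400L)))
  expect_equal(gA$introns, data.frame(start = 201L, end = 300L))
  expect_equal(gA$transcripts$gA.1$introns,
               data.frame(start = 201L, end = 300L))
  # single-exon transcript has no introns
  one <- assemble_gene_models(parse_gff3(c(
    "chr1\ts\tgene\t10\t90\t.\t+\t.\tID=g",
    "chr1\ts\tmRNA\t10\t90\t.\t+\t.\tID=g.1;Parent=g",
    "chr1\ts\texon\t10\t90\t.\t+\t.\tParent=g.1")))
  expect_equal(nrow(one$g$introns), 0L)
})

test_that("multi-transcript genes get per-transcript introns and a gene-level union", {
  f <- parse_gff3(c(
    "chr1\ts\tgene\t100\t500\t.\t+\t.\tID=g",
    "chr1\ts\tmRNA\t100\t500\t.\t+\t.\tID=g.1;Parent=g",
    "chr1\ts\texon\t100\t200\t.\t+\t.\tParent=g.1",
    "chr1\ts\texon\t401\t500\t.\t+\t.\tParent=g.1",
    "chr1\ts\tmRNA\t100\t500\t.\t+\t.\tID=g.2;Parent=g",
    "chr1\ts\texon\t100\t250\t.\t+\t.\tParent=g.2",
    "chr1\ts\texon\t301\t500\t.\t+\t.\tParent=g.2"))
  m <- assemble_gene_models(f)$g
  # hand-computed complements within each transcript's exon span
  expect_equal(m$transcripts$g.1$introns,
               data.frame(start = 201L, end = 400L))
  expect_equal(m$transcripts$g.2$introns,
               data.frame(start = 251L, end = 300L))
  # union across isoforms, and its complement as gene-level introns
  expect_equal(m$exon_union, data.frame(start = c(100L, 301L),
                                        end = c(250L, 500L)))
  expect_equal(m$introns, data.frame(start = 251L, end = 300L))
})

test_that("model assembly reports structural errors and orphans", {
  bad <- parse_gff3(c(
    "chr1\ts\tgene\t1\t300\t.\t+\t.\tID=g",
    "chr1\ts\tmRNA\t1\t300\t.\t+\t.\tID=g.1;Parent=g",
    "chr1\ts\texon\t1\t100\t.\t+\t.\tParent=g.1",
    "chr1\ts\texon\t50\t200\t.\t+\t.\tParent=g.1"))
  expect_error(assemble_gene_models(bad), "overlapping exons")

  orphan <- parse_gff3(c(
    "chr1\ts\tgene\t1\t300\t.\t+\t.\tID=g",
    "chr1\ts\texon\t1\t100\t.\t+\t.\tParent=nosuch"))
  m <- assemble_gene_models(orphan)
  expect_equal(nrow(attr(m, "orphans")), 1L)
  expect_equal(attr(m, "orphans")$parent, "nosuch")
})

test_that("unknown strand is treated as '+' with a warning", {
  f <- parse_gff3(c("chr1\ts\tgene\t1\t90\t.\t.\t.\tID=g",
                    "chr1\ts\tmRNA\t1\t90\t.\t.\t.\tID=g.1;Parent=g",
                    "chr1\ts\texon\t1\t90\t.\t.\t.\tParent=g.1"))
  expect_warning(m <- assemble_gene_models(f), "unknown strand")
  expect_equal(m$g$strand, "+")
})

test_that("exons and introns of a transcript tile the exon span exactly", {
  set.seed(11)
  for (rep in 1:20) {
    g <- random_gene()
    span <- g$exon_union$end[nrow(g$exon_union)] - g$exon_union$start[1L] + 1L
    tiles <- sum(g$exon_union$end - g$exon_union$start + 1L) +
      sum(g$introns$end - g$introns$start + 1L)
    expect_equal(tiles, span)
  }
})

test_that("read_fasta takes the first header token, uppercases, and rejects duplicates", {
  p <- withr::local_tempfile(lines = c(">g1", "acgt",
                                       ">g2 some description", "TTAA"))
  seqs <- read_fasta(p)
  expect_equal(seqs, c(g1 = "ACGT", g2 = "TTAA"))

  dup <- withr::local_tempfile(lines = c(">g1", "ACGT", ">g1", "TTTT"))
  expect_error(read_fasta(dup), "duplicate")

  odd <- withr::local_tempfile(lines = c(">g1", "AC9T"))
  expect_warning(read_fasta(odd, "nt"), "non-IUPAC.*position 3")
})

test_that("unspliced sequence extraction is an exact forward-strand slice", {
  g <- make_gene("g", "c", 2L, 4L, "+",
                 data.frame(start = 2L, end = 4L))
  expect_equal(extract_unspliced_sequence(g, "AACGTT"), "ACG")
  gfull <- make_gene("g", "c", 1L, 6L, "-",
                     data.frame(start = 1L, end = 6L))
  expect_equal(extract_unspliced_sequence(gfull, "AACGTT"), "AACGTT")
  gbad <- make_gene("g", "c", 3L, 9L, "+",
                    data.frame(start = 3L, end = 9L))
  expect_error(extract_unspliced_sequence(gbad, "AACGTT"), "exceeds")
  # length always equals the gene span
  set.seed(4)
  chrom <- random_dna(500)
  for (rep in 1:10) {
    s <- sample(1:400, 1L); e <- s + sample(0:99, 1L)
    g <- make_gene("g", "c", s, e, "+", data.frame(start = s, end = e))
    expect_equal(nchar(extract_unspliced_sequence(g, chrom)), e - s + 1L)
  }
})
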