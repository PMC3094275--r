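test_that("identification filtering applies score and length thresholds", {
  rows <- data.frame(sequence = c("AAAAA", "AAAAAA", "AAAAAAA"),
                     score = c(50, 60, 70), stringsAsFactors = FALSE)
  expect_equal(nrow(suppressMessages(
    filter_identifications(rows, 0, 0L))), 3L)
  expect_equal(suppressMessages(
    filter_identifications(rows, 0, 6L))$sequence,
    c("AAAAAA", "AAAAAAA"))
  # 8 rows: 3 below the score cutoff, then 1 more below the length cutoff
  tab <- data.frame(
    sequence = c("AAAAAAA", "CCCCCCC", "DDDDD", "EEEEEEE", "FFFFFFF",
                 "GGGGGGG", "HHHHHHH", "KKKKKKK"),
    score = c(10, 15, 80, 19, 90, 85, 70, 60), stringsAsFactors = FALSE)
  kept <- suppressMessages(filter_identifications(tab, 20, 6L))
  expect_equal(nrow(kept), 4L)
  expect_setequal(kept$sequence, c("FFFFFFF", "GGGGGGG", "HHHHHHH",
                                   "KKKKKKK"))
  expect_error(filter_identifications(
    data.frame(sequence = "AAAA"), min_score = 10), "score")
})

test_that("peptide IDs are per-source serials in input order", {
  p <- data.frame(sequence = c("A", "B", "C", "D"),
                  source_db = c("P", "C", "P", "G"),
                  stringsAsFactors = FALSE)
  out <- assign_peptide_ids(p)
  expect_equal(out$peptide_id, c("P1", "C1", "P2", "G1"))
  # serials are gap-free per source and the map is a bijection
  p2 <- data.frame(sequence = letters[1:10],
                   source_db = rep(c("P", "C"), 5L),
                   stringsAsFactors = FALSE)
  ids <- assign_peptide_ids(p2)$peptide_id
  expect_equal(sort(ids[seq(1, 10, 2)]), paste0("P", 1:5))
  expect_false(anyDuplicated(ids) > 0L)
  expect_match(ids, "^[PCTG][0-9]+$")
})

test_that("peptide GFF3 lines carry parent:peptideID notation and metadata", {
  f <- peptide_to_gff3("P62531", "LOC_Os06g01230.1", "chr6", 501L, 530L,
                       "+", "P", "known", FALSE)
  expect_equal(f$type, "peptide")
  expect_equal(f$source, "pgmap:P")
  expect_equal(gff3_attr(f$attributes, "ID"), "LOC_Os06g01230.1:P62531")
  expect_equal(gff3_attr(f$attributes, "Parent"), "LOC_Os06g01230.1")

  fi <- peptide_to_gff3("C3", "gA.1", "chr1", 10L, 39L, "-", "C",
                        "intronic", TRUE)
  expect_match(fi$attributes, "cluster=intronic;novel=true")
  expect_error(peptide_to_gff3("G1", NA, "chr1", 1L, 30L, "+", "G",
                               "intergenic", TRUE), "intergenic")
})

test_that("annotation update appends peptide lines inside their gene blocks", {
  orig <- parse_gff3(fixture_gff3_lines())
  expect_identical(update_annotation(orig, orig[0, ]), orig)

  peps <- rbind(
    peptide_to_gff3("P1", "gA.1", "chr1", 110L, 139L, "+", "P", "known",
                    FALSE),
    peptide_to_gff3("C1", "gA.1", "chr1", 190L, 219L, "+", "C",
                    "exon_donor_spanning", TRUE),
    peptide_to_gff3("P2", "gB.1", "chr1", 810L, 839L, "-", "P", "known",
                    FALSE))
  upd <- update_annotation(orig, peps)
  expect_equal(nrow(upd), nrow(orig) + 3L)
  # original lines byte-identical and in their original relative order
  orig_feat <- write_gff3(orig)[-1L]
  upd_feat <- write_gff3(upd)[-1L]
  expect_identical(upd_feat[upd_feat %in% orig_feat], orig_feat)
  # placement: gA's peptides come right after gA's block (row 7), before gB
  expect_equal(upd$type[7:8], c("peptide", "peptide"))
  expect_equal(upd$parent[7:8], c("gA.1", "gA.1"))
  expect_equal(upd$type[nrow(upd)], "peptide")
  expect_equal(upd$parent[nrow(upd)], "gB.1")
  # re-parsing: every Parent resolves, count preserved
  re <- parse_gff3(write_gff3(upd))
  expect_equal(nrow(re), nrow(orig) + 3L)
  parents <- re$parent[!is.na(re$parent)]
  expect_true(all(parents %in% re$feature_id))

  orphan <- peptide_to_gff3("G9", "nosuch.1", "chr1", 1L, 30L, "+", "G",
                            "known", FALSE)
  expect_error(update_annotation(orig, orphan), "unknown Parent")
})

test_that("non-block-sorted annotation is re-grouped with a warning", {
  lines <- fixture_gff3_lines()
  shuffled <- parse_gff3(lines[c(2, 8, 3, 9, 4, 10, 5, 11, 6, 7)])
  pep <- peptide_to_gff3("P1", "gA.1", "chr1", 110L, 139L, "+", "P",
                         "known", FALSE)
  expect_warning(upd <- update_annotation(shuffled, pep),
                 "not block-sorted")
  roots <- upd$parent
  gA_rows <- which(upd$feature_id == "gA" |
                     (!is.na(upd$parent) & upd$parent %in% c("gA", "gA.1")))
  expect_equal(gA_rows, seq(min(gA_rows), max(gA_rows)))
})

report_fixture <- function() {
  peptides <- data.frame(
    peptide_id = c("P1", "P2", "C1", "C2", "G1"),
    gene_id = c("gA", "gA", "gA", "gB", NA),
    sequence = c("AAAAAAA", "CCCCCCC", "DDDDDDD", "EEEEEEE", "FFFFFFF"),
    source_db = c("P", "P", "C", "C", "G"),
    cluster = c("known", "known", "intronic", "exon_donor_spanning",
                "intergenic"),
    is_novel = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    chrom = "chr1", start = c(110L, 150L, 220L, 650L, 950L),
    end = c(139L, 179L, 249L, 679L, 979L), strand = "+",
    ambiguous = FALSE, multi_gene = FALSE, score = 50,
    stringsAsFactors = FALSE)
  genes <- rbind(
    summarize_gene("gA", peptides[peptides$gene_id %in% "gA", ], "chr1"),
    summarize_gene("gB", peptides[peptides$gene_id %in% "gB", ], "chr1"))
  genes$gene_start <- c(101L, 601L)
  list(genes = genes, peptides = peptides)
}

test_that("reports enforce master-slave integrity and deterministic order", {
  fx <- report_fixture()
  gp <- withr::local_tempfile(fileext = ".csv")
  pp <- withr::local_tempfile(fileext = ".csv")
  write_reports(fx$genes, fx$peptides, gp, pp)
  g <- utils::read.csv(gp, stringsAsFactors = FALSE)
  p <- utils::read.csv(pp, stringsAsFactors = FALSE)
  expect_equal(nrow(g), 2L)
  expect_equal(nrow(p), 5L)
  # group-by over the peptides CSV reproduces the genes CSV counts
  for (i in seq_len(nrow(g))) {
    rows <- p[!is.na(p$gene_id) & p$gene_id == g$gene_id[i], ]
    expect_equal(g$total_peptides[i], nrow(rows))
    expect_equal(g$novel_peptides[i], sum(rows$is_novel))
    expect_equal(g$n_intronic[i],
                 sum(rows$is_novel & rows$cluster == "intronic"))
    expect_equal(g$n_donor[i],
                 sum(rows$is_novel & rows$cluster == "exon_donor_spanning"))
  }
  # a tampered total is refused
  bad <- fx$genes; bad$total_peptides[1L] <- 99L
  expect_error(write_reports(bad, fx$peptides, gp, pp), "integrity")
  # empty inputs give header-only CSVs
  write_reports(fx$genes[0, ], fx$peptides[0, ], gp, pp)
  expect_equal(length(readLines(gp)), 1L)
  expect_equal(length(readLines(pp)), 1L)
})

test_that("relational export validates foreign keys and reconstructs joins", {
  fx <- report_fixture()
  genes <- fx$genes
  products <- data.frame(
    product_id = c("gA.1", "gA.1", "gA", "gB.1", "gB.1", "gB"),
    gene_id = c("gA", "gA", "gA", "gB", "gB", "gB"),
    ptype = c("protein", "cdna", "unspliced_mrna",
              "protein", "cdna", "unspliced_mrna"),
    length = c(100L, 400L, 300L, 80L, 350L, 300L),
    stringsAsFactors = FALSE)
  dir <- withr::local_tempdir()
  paths <- export_relational(genes, products, fx$peptides, dir)
  expect_true(all(file.exists(paths)))
  # joining the exported tables on gene_id reconstructs the associations
  prot <- utils::read.csv(paths[["protein"]], stringsAsFactors = FALSE)
  pep <- utils::read.csv(paths[["peptide"]], stringsAsFactors = FALSE)
  gene <- utils::read.csv(paths[["gene"]], stringsAsFactors = FALSE)
  joined <- merge(pep, gene, by = "gene_id")
  expect_equal(nrow(joined), sum(!is.na(fx$peptides$gene_id)))
  expect_setequal(merge(prot, gene, by = "gene_id")$product_id,
                  c("gA.1", "gB.1"))
  # a peptide pointing at a missing gene is rejected
  badp <- fx$peptides; badp$gene_id[1L] <- "missing"
  expect_error(export_relational(genes, products, badp, dir),
               "dangling")
  badprod <- products; badprod$gene_id[1L] <- NA
  expect_error(export_relational(genes, badprod, fx$peptides, dir),
               "no gene_id")
})
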