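# Independent oracles used to validate the package's implementations.
# These are deliberately written from first principles (hand-rolled codon
# table, per-base labeling, all-offsets scanning) and share no code with
# the package internals they check.

ORACLE_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1L]]),
        collapse = "")
}

oracle_translate <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- ORACLE_CODE[codons]
  aa[is.na(aa)] <- "X"   # any codon containing N (or other) -> X
  paste(aa, collapse = "")
}

oracle_six_frame <- function(nt) {
  rc <- oracle_revcomp(nt)
  out <- character()
  for (f in 0:2) {
    out[[paste0("F", f + 1L)]] <- oracle_translate(substring(nt, f + 1L))
  }
  for (f in 0:2) {
    out[[paste0("R", f + 1L)]] <- oracle_translate(substring(rc, f + 1L))
  }
  out
}

# all-offsets brute-force peptide search over the six frames
oracle_find_matches <- function(pep, target, il_equivalent = TRUE) {
  canon <- function(x) if (il_equivalent) chartr("I", "L", x) else x
  frames <- oracle_six_frame(target)
  n <- nchar(target)
  L <- nchar(pep)
  hits <- list()
  for (fr in names(frames)) {
    aa <- frames[[fr]]
    f <- as.integer(substr(fr, 2L, 2L)) - 1L
    if (nchar(aa) < L) next
    for (a in 0:(nchar(aa) - L)) {
      if (canon(substr(aa, a + 1L, a + L)) == canon(pep)) {
        if (startsWith(fr, "F")) {
          ls <- f + 3L * a + 1L; le <- ls + 3L * L - 1L
        } else {
          ls <- n - (f + 3L * a + 3L * L) + 1L; le <- n - f - 3L * a
        }
        hits[[length(hits) + 1L]] <- data.frame(
          frame = fr, aa_offset = a, local_start = ls, local_end = le,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) {
    out <- data.frame(frame = character(), aa_offset = integer(),
                      local_start = integer(), local_end = integer(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$frame, out$aa_offset), , drop = FALSE]
}

# per-base brute-force labeler: tag every base of [s, e] exon or intron,
# then classify from the label-run pattern read in transcription order
oracle_classify <- function(s, e, gene) {
  E <- gene$exon_union
  exonic <- vapply(s:e, function(p) any(E$start <= p & p <= E$end),
                   logical(1L))
  if (gene$strand == "-") exonic <- rev(exonic)
  runs <- rle(exonic)$values
  cluster <- if (all(runs)) "known"
    else if (all(!runs)) "intronic"
    else if (runs[1L]) "exon_donor_spanning"
    else "exon_acceptor_spanning"
  list(cluster = cluster, boundaries_crossed = length(runs) - 1L)
}

# a minimal gene-model-shaped object for classifier tests
make_gene <- function(gene_id, seqid, start, end, strand, exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  introns <- if (nrow(exons) > 1L) {
    data.frame(start = exons$end[-nrow(exons)] + 1L,
               end = exons$start[-1L] - 1L)
  } else {
    data.frame(start = integer(), end = integer())
  }
  structure(list(gene_id = gene_id, seqid = seqid, start = start,
                 end = end, strand = strand, transcripts = list(),
                 exon_union = exons, introns = introns,
                 unspliced_seq = NULL),
            class = "gene_model")
}

# random multi-exon gene (exon blocks separated by gaps) for properties
random_gene <- function(id = "G1", strand = sample(c("+", "-"), 1L)) {
  n_ex <- sample(2:5, 1L)
  lens <- sample(30:120, n_ex, replace = TRUE)
  gaps <- sample(20:100, n_ex - 1L, replace = TRUE)
  start <- sample(1:500, 1L)
  pos <- start
  ex <- data.frame(start = integer(), end = integer())
  for (i in seq_len(n_ex)) {
    ex <- rbind(ex, data.frame(start = pos, end = pos + lens[i] - 1L))
    pos <- pos + lens[i] + if (i < n_ex) gaps[i] else 0L
  }
  make_gene(id, "chrT", start, max(ex$end), strand, ex)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# small GFF3 fixture: two genes on one chromosome with mRNA/exon/CDS rows
fixture_gff3_lines <- function() {
  c("##gff-version 3",
    "chr1\ttest\tgene\t101\t400\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t101\t400\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttest\texon\t101\t200\t.\t+\t.\tParent=gA.1",
    "chr1\ttest\texon\t301\t400\t.\t+\t.\tParent=gA.1",
    "chr1\ttest\tCDS\t121\t200\t0.9\t+\t0\tParent=gA.1",
    "chr1\ttest\tCDS\t301\t380\t.\t+\t0\tParent=gA.1",
    "chr1\ttest\tgene\t601\t900\t.\t-\t.\tID=gB",
    "chr1\ttest\tmRNA\t601\t900\t.\t-\t.\tID=gB.1;Parent=gB",
    "chr1\ttest\texon\t601\t700\t.\t-\t.\tParent=gB.1",
    "chr1\ttest\texon\t801\t900\t.\t-\t.\tParent=gB.1")
}
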