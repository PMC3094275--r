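# ---------------------------------------------------------------------------
# Peptide novelty screening and genomic-context classification
#
# A peptide is novel if it does not occur as a substring of any entry in
# the reference protein database. Novelty alone does not imply a novel
# genomic feature: a novel peptide wholly inside a known exon merely
# reflects database incompleteness. The classifier below assigns each
# gene-mapped peptide one of four clusters -- known (exonic), intronic,
# exon-donor-spanning, exon-acceptor-spanning -- with intergenic as a
# fifth label for peptides outside every gene.
# ---------------------------------------------------------------------------

CLUSTER_LEVELS <- c("known", "intronic", "exon_donor_spanning",
                    "exon_acceptor_spanning", "intergenic")

#' Screen peptides for novelty against a protein database
#'
#' A peptide is novel iff its sequence occurs as a substring of no protein
#' entry (under I/L equivalence when configured). Peptides identified from
#' the protein database itself (source P) are never novel by construction.
#'
#' @param sequences Character vector of peptide sequences.
#' @param protein_db Named character vector of protein sequences.
#' @param source_db Optional character vector of source tags (P/C/T/G);
#'   source-P peptides are forced non-novel (and this is asserted: a
#'   source-P peptide absent from the database is an input error).
#' @param il_equivalent Treat I and L as interchangeable (default TRUE).
#' @return Logical vector: TRUE = novel.
#' @export
novelty_screen <- function(sequences, protein_db, source_db = NULL,
                           il_equivalent = TRUE) {
  if (!length(protein_db)) {
    if (length(sequences) &&
        (is.null(source_db) || any(source_db != "P"))) {
      warning("empty protein database: every screened peptide is novel")
    }
    return(rep(TRUE, length(sequences)) &
             (if (is.null(source_db)) TRUE else source_db != "P"))
  }
  db <- canon_il(unname(protein_db), il_equivalent)
  novel <- vapply(canon_il(sequences, il_equivalent), function(p) {
    !any(grepl(p, db, fixed = TRUE))
  }, logical(1L), USE.NAMES = FALSE)
  if (!is.null(source_db)) {
    bad <- which(source_db == "P" & novel)
    if (length(bad)) {
      stop("source-P peptide not found in the protein database: ",
           sequences[bad[1L]])
    }
    novel[source_db == "P"] <- FALSE
  }
  novel
}

#' Classify a gene-mapped peptide interval into a genomic-context cluster
#'
#' With E the union of exons across the gene's transcripts and the
#' non-exonic remainder of the gene span treated as intronic, a peptide
#' interval wholly inside one exon block is \code{known}; wholly inside
#' one intron is \code{intronic}; otherwise it crosses one or more
#' exon/intron junctions. Donor versus acceptor is decided in
#' transcription orientation: crossing an exon-to-intron junction (the
#' intron's 5' splice site) makes the peptide
#' \code{exon_donor_spanning}; crossing an intron-to-exon junction (3'
#' splice site) makes it \code{exon_acceptor_spanning}. When several
#' junctions are crossed the cluster is taken from the first junction in
#' transcription direction and all crossed junction coordinates are
#' recorded.
#'
#' @param chrom_start,chrom_end Peptide interval (chromosome coordinates,
#'   1-based closed); must lie within the gene span.
#' @param gene The gene model the peptide is assigned to.
#' @return list(cluster, boundaries_crossed, junctions) where junctions is
#'   a character vector of "left|right" base coordinates of each crossed
#'   junction, in transcription order.
#' @export
classify_peptide <- function(chrom_start, chrom_end, gene) {
  s <- chrom_start; e <- chrom_end
  if (s < gene$start || e > gene$end || s > e) {
    stop("peptide interval [", s, ",", e, "] not within gene '",
         gene$gene_id, "' span [", gene$start, ",", gene$end, "]")
  }
  E <- gene$exon_union
  if (nrow(E) && any(E$start <= s & e <= E$end)) {
    return(list(cluster = "known", boundaries_crossed = 0L,
                junctions = character()))
  }
  jn <- gene_junctions(gene)
  crossed <- jn[jn$pos >= s & jn$pos < e, , drop = FALSE]
  if (!nrow(crossed)) {
    return(list(cluster = "intronic", boundaries_crossed = 0L,
                junctions = character()))
  }
  # transcription order: ascending coordinates on '+', descending on '-'
  ord <- order(crossed$pos, decreasing = (gene$strand == "-"))
  crossed <- crossed[ord, , drop = FALSE]
  list(
    cluster = crossed$kind[1L],
    boundaries_crossed = nrow(crossed),
    junctions = paste0(crossed$pos, "|", crossed$pos + 1L)
  )
}

# Every boundary between an exon-union block and adjacent non-exonic
# sequence within the gene span, as the coordinate of its left base, typed
# donor/acceptor in transcription orientation.
gene_junctions <- function(gene) {
  E <- gene$exon_union
  if (!nrow(E)) {
    return(data.frame(pos = integer(), kind = character()))
  }
  # exon-end boundaries (exon | non-exon, reading left to right)
  ee <- E$end[E$end < gene$end]
  # exon-start boundaries (non-exon | exon)
  es <- E$start[E$start > gene$start] - 1L
  plus <- gene$strand == "+"
  data.frame(
    pos = c(ee, es),
    kind = c(rep(if (plus) "exon_donor_spanning" else
                 "exon_acceptor_spanning", length(ee)),
             rep(if (plus) "exon_acceptor_spanning" else
                 "exon_donor_spanning", length(es))),
    stringsAsFactors = FALSE
  )
}

#' Summarize novelty calls per gene
#'
#' Novel features are novel peptides in the intronic, donor-spanning or
#' acceptor-spanning clusters; novel peptides wholly inside known coding
#' regions count as novel peptides but not as novel features.
#'
#' @param gene_id Gene identifier.
#' @param calls data.frame of per-peptide calls for this gene, with at
#'   least columns cluster and is_novel.
#' @param seqid Optional chromosome name carried into the summary.
#' @return One-row data.frame with total/novel/per-cluster counts and a
#'   has_novel_features flag.
#' @export
summarize_gene <- function(gene_id, calls, seqid = NA_character_) {
  n_int <- sum(calls$is_novel & calls$cluster == "intronic")
  n_don <- sum(calls$is_novel & calls$cluster == "exon_donor_spanning")
  n_acc <- sum(calls$is_novel & calls$cluster == "exon_acceptor_spanning")
  data.frame(
    gene_id = gene_id, chromosome = seqid,
    total_peptides = nrow(calls),
    novel_peptides = sum(calls$is_novel),
    n_intronic = n_int, n_donor = n_don, n_acceptor = n_acc,
    n_known_novel = sum(calls$is_novel & calls$cluster == "known"),
    has_novel_features = (n_int + n_don + n_acc) > 0L,
    stringsAsFactors = FALSE
  )
}
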