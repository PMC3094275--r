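# ---------------------------------------------------------------------------
# Assignment of chromosome-located peptide hits to genes
# ---------------------------------------------------------------------------

#' Build an interval index over gene spans
#'
#' @param models A gene_model_set.
#' @param chromosomes Character vector of all chromosome names the index
#'   should know about; defaults to the chromosomes carrying genes. Queries
#'   on chromosomes outside this set are an error; queries on a known
#'   chromosome without genes return no overlap.
#' @return A gene_index object answering interval-intersection queries.
#' @export
build_gene_index <- function(models, chromosomes = NULL) {
  gene_ids <- names(models)
  seqids <- vapply(models, `[[`, character(1L), "seqid")
  if (is.null(chromosomes)) chromosomes <- unique(seqids)
  gr <- GenomicRanges::GRanges(
    seqnames = factor(seqids, levels = chromosomes),
    ranges = IRanges::IRanges(
      start = vapply(models, `[[`, numeric(1L), "start"),
      end = vapply(models, `[[`, numeric(1L), "end")
    ),
    gene_id = gene_ids
  )
  structure(list(granges = gr, models = models, chromosomes = chromosomes),
            class = "gene_index")
}

#' Assign located hits to overlapping genes
#'
#' A hit is assigned to every gene whose closed span shares at least one
#' base with the hit interval; containment and partial overlap both
#' qualify. Assignment is strand-agnostic (hit strand vs gene strand is
#' recorded downstream in the peptide report). An empty assignment marks
#' the hit intergenic.
#'
#' @param hits data.frame with seqid, chrom_start, chrom_end columns.
#' @param index A gene_index.
#' @return A list (one element per hit row) of character vectors of
#'   gene_ids; empty vector for intergenic hits.
#' @export
assign_to_genes <- function(hits, index) {
  if (!nrow(hits)) return(list())
  unknown <- setdiff(unique(hits$seqid), index$chromosomes)
  if (length(unknown)) {
    stop("hit chromosome(s) absent from gene index: ",
         paste(unknown, collapse = ", "))
  }
  q <- GenomicRanges::GRanges(
    seqnames = factor(hits$seqid, levels = index$chromosomes),
    ranges = IRanges::IRanges(hits$chrom_start, hits$chrom_end)
  )
  ov <- GenomicRanges::findOverlaps(q, index$granges)
  res <- rep(list(character()), nrow(hits))
  if (length(ov)) {
    sp <- split(index$granges$gene_id[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
    for (k in names(sp)) res[[as.integer(k)]] <- unname(sp[[k]])
  }
  res
}

#' Partition hits into genic and intergenic sets
#'
#' Every hit lands in exactly one partition. Genic hits are expanded to one
#' row per (hit, gene) pair with a \code{gene_id} column and a
#' \code{multi_gene} flag for hits overlapping more than one gene.
#' Intergenic hits carry no parent; they are excluded from gene GFF3
#' blocks but appear in the peptide report with cluster
#' \code{"intergenic"}.
#'
#' @param hits data.frame of chromosome-located hits.
#' @param index A gene_index.
#' @return list(genic = data.frame with gene_id and multi_gene columns,
#'   intergenic = data.frame of unassigned hits).
#' @export
flag_intergenic <- function(hits, index) {
  assignments <- assign_to_genes(hits, index)
  n_genes <- lengths(assignments)
  inter <- hits[n_genes == 0L, , drop = FALSE]
  rownames(inter) <- NULL
  genic_rows <- which(n_genes > 0L)
  genic <- hits[rep(genic_rows, n_genes[genic_rows]), , drop = FALSE]
  genic$gene_id <- unlist(assignments[genic_rows], use.names = FALSE)
  genic$multi_gene <- rep(n_genes[genic_rows] > 1L, n_genes[genic_rows])
  rownames(genic) <- NULL
  list(genic = genic, intergenic = inter)
}
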