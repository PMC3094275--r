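# ---------------------------------------------------------------------------
# Identification filtering, peptide IDs, GFF3 evidence lines, master-slave
# reports and relational export
# ---------------------------------------------------------------------------

#' Read a peptide identification table
#'
#' Accepts TSV or CSV (auto-detected from the header line) with at least
#' the columns \code{sequence} and \code{source_db}, and optionally
#' \code{score}.
#'
#' @param path Path to the table.
#' @return data.frame with sequence, source_db and (if present) score.
#' @export
read_identifications <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, quote = "\"")
  required <- c("sequence", "source_db")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("identification table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  bad <- !df$source_db %in% c("P", "C", "T", "G")
  if (any(bad)) {
    stop("invalid source_db tag(s): ",
         paste(unique(df$source_db[bad]), collapse = ", "),
         " (expected P, C, T or G)")
  }
  df$sequence <- toupper(df$sequence)
  df
}

#' Filter identifications on score and peptide length
#'
#' Mirrors the usual search-engine post-filter that keeps only
#' high-confidence identifications. Dropped-row counts per criterion are
#' reported via \code{message()}.
#'
#' @param rows Identification data.frame (sequence, optional score).
#' @param min_score Minimum score (rows with missing score fail when
#'   min_score > 0; a table without a score column is an error then).
#' @param min_length Minimum peptide length in residues.
#' @return The surviving rows.
#' @export
filter_identifications <- function(rows, min_score = 0, min_length = 6L) {
  if (min_score > 0 && !"score" %in% names(rows)) {
    stop("min_score > 0 requires a 'score' column")
  }
  keep_score <- if ("score" %in% names(rows) && min_score > 0) {
    !is.na(rows$score) & rows$score >= min_score
  } else {
    rep(TRUE, nrow(rows))
  }
  keep_len <- nchar(rows$sequence) >= min_length
  message(sum(!keep_score), " row(s) dropped by score < ", min_score, "; ",
          sum(keep_score & !keep_len), " further dropped by length < ",
          min_length)
  out <- rows[keep_score & keep_len, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign serial peptide IDs per identification source
#'
#' IDs are the source letter (P, C, T or G) followed by the 1-based serial
#' number of the peptide within that source, in input order: the third
#' protein-source peptide is \code{P3}.
#'
#' @param peptides data.frame with a source_db column.
#' @return The data.frame with a peptide_id column prepended.
#' @export
assign_peptide_ids <- function(peptides) {
  serial <- stats::ave(seq_len(nrow(peptides)), peptides$source_db,
                       FUN = seq_along)
  peptides$peptide_id <- paste0(peptides$source_db, serial)
  peptides[, c("peptide_id", setdiff(names(peptides), "peptide_id")),
           drop = FALSE]
}

#' Convert a classified peptide hit to a GFF3 feature row
#'
#' Emits a feature of type \code{"peptide"} whose source column encodes
#' the identification source (e.g. \code{"pgmap:P"}), with attributes
#' \code{ID=<parent>:<peptide_id>}, \code{Parent=<parent>}, plus
#' \code{cluster=} and \code{novel=} tags.
#'
#' @param peptide_id Assigned peptide ID (e.g. "P62531").
#' @param parent Parent feature ID the peptide attaches to (e.g.
#'   "LOC_Os06g01230.1"); intergenic peptides have no parent and are
#'   exported separately (see \code{intergenic_gff3}).
#' @param seqid,start,end,strand Chromosome location of the peptide.
#' @param source_db Identification source tag (P/C/T/G).
#' @param cluster Genomic-context cluster label.
#' @param novel Logical novelty flag.
#' @param source_prefix Prefix for the GFF3 source column.
#' @return One-row feature data.frame compatible with \code{write_gff3}.
#' @export
peptide_to_gff3 <- function(peptide_id, parent, seqid, start, end, strand,
                            source_db, cluster, novel,
                            source_prefix = "pgmap") {
  if (is.na(parent) || !nzchar(parent)) {
    stop("peptide '", peptide_id, "' has no parent gene; intergenic ",
         "peptides belong in the intergenic export, not in gene blocks")
  }
  data.frame(
    seqid = seqid, source = paste0(source_prefix, ":", source_db),
    type = "peptide", start = as.integer(start), end = as.integer(end),
    score = ".", strand = strand, phase = ".",
    attributes = gff3_attributes(
      id = paste0(parent, ":", peptide_id), parent = parent,
      cluster = cluster, novel = tolower(as.character(novel))
    ),
    feature_id = paste0(parent, ":", peptide_id), parent = parent,
    stringsAsFactors = FALSE
  )
}

#' GFF3 features for intergenic peptide evidence
#'
#' Intergenic peptides have no Parent; their seqid is the chromosome and
#' the ID is the bare peptide ID.
#'
#' @param peptides data.frame with peptide_id, seqid, chrom_start,
#'   chrom_end, strand, source_db columns.
#' @param source_prefix Prefix for the GFF3 source column.
#' @return Feature data.frame compatible with \code{write_gff3}.
#' @export
intergenic_gff3 <- function(peptides, source_prefix = "pgmap") {
  if (!nrow(peptides)) return(empty_gff3())
  data.frame(
    seqid = peptides$seqid,
    source = paste0(source_prefix, ":", peptides$source_db),
    type = "peptide", start = peptides$chrom_start,
    end = peptides$chrom_end, score = ".", strand = peptides$strand,
    phase = ".",
    attributes = paste0("ID=", peptides$peptide_id,
                        ";cluster=intergenic;novel=true"),
    feature_id = peptides$peptide_id, parent = NA_character_,
    stringsAsFactors = FALSE
  )
}

# root gene of a feature id: follow Parent links upward
feature_roots <- function(features) {
  id2parent <- stats::setNames(features$parent, features$feature_id)
  id2parent <- id2parent[!is.na(names(id2parent))]
  root_of <- function(x) {
    seen <- character()
    while (x %in% names(id2parent) && !is.na(id2parent[[x]])) {
      if (x %in% seen) stop("Parent cycle at feature '", x, "'")
      seen <- c(seen, x)
      x <- id2parent[[x]]
    }
    x
  }
  key <- ifelse(!is.na(features$feature_id), features$feature_id,
                ifelse(!is.na(features$parent), features$parent,
                       paste0(".row", seq_len(nrow(features)))))
  vapply(key, root_of, character(1L), USE.NAMES = FALSE)
}

#' Append peptide evidence lines to their gene blocks
#'
#' Inserts each peptide feature immediately after the last line of the
#' block of features rooted at its parent gene (a gene's block is the
#' maximal run of consecutive lines whose ID/Parent chain roots at that
#' gene). Original feature rows are passed through untouched, so their
#' serialized lines are byte-identical; input that is not block-sorted is
#' re-grouped gene-wise first, with a warning.
#'
#' @param original Feature data.frame of the annotation to update.
#' @param peptide_features Feature data.frame of peptide evidence lines
#'   (each must carry a Parent resolving into \code{original}).
#' @return The updated feature data.frame.
#' @export
update_annotation <- function(original, peptide_features) {
  if (!nrow(peptide_features)) return(original)
  roots <- feature_roots(original)
  known_ids <- original$feature_id[!is.na(original$feature_id)]
  orphan <- !peptide_features$parent %in% known_ids
  if (any(orphan)) {
    stop("peptide feature(s) with unknown Parent: ",
         paste(unique(peptide_features$parent[orphan]), collapse = ", "))
  }
  # resolve each peptide's parent to its root gene
  both <- rbind(original[, c("feature_id", "parent")],
                data.frame(feature_id = paste0(".pep", seq_len(nrow(peptide_features))),
                           parent = peptide_features$parent,
                           stringsAsFactors = FALSE))
  pep_roots <- feature_roots(both)[nrow(original) + seq_len(nrow(peptide_features))]

  ord <- seq_len(nrow(original))
  if (anyDuplicated(rle(roots)$values)) {
    warning("annotation is not block-sorted by gene; re-grouping gene-wise")
    ord <- order(match(roots, unique(roots)))
    roots <- roots[ord]
  }
  block_last <- vapply(unique(roots), function(r) max(which(roots == r)),
                       integer(1L))
  out_idx <- list()
  pep_by_root <- split(seq_len(nrow(peptide_features)), pep_roots)
  pos <- 0L
  pieces <- list()
  for (b in seq_along(block_last)) {
    root <- names(block_last)[b]
    first <- if (b == 1L) 1L else block_last[b - 1L] + 1L
    pieces[[length(pieces) + 1L]] <- original[ord[first:block_last[b]], ,
                                              drop = FALSE]
    if (root %in% names(pep_by_root)) {
      pieces[[length(pieces) + 1L]] <-
        peptide_features[pep_by_root[[root]], , drop = FALSE]
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  attr(out, "gff_version") <- attr(original, "gff_version")
  out
}

#' Write the master-slave gene and peptide CSV reports
#'
#' Validates master-slave integrity first (gene totals must equal
#' group-by counts over the peptide rows) and refuses to write otherwise.
#' Row order is deterministic: genes by chromosome then start, peptides by
#' gene then peptide ID (intergenic peptides last, by chromosome and
#' start). CSV dialect is fixed: comma-separated, double-quote escaping,
#' LF line endings, header row.
#'
#' @param genes_table Per-gene summary data.frame (gene_id, chromosome,
#'   gene_start, total_peptides, novel_peptides, n_intronic, n_donor,
#'   n_acceptor, n_known_novel, has_novel_features).
#' @param peptides_table Per-peptide data.frame (peptide_id, gene_id,
#'   sequence, source_db, cluster, is_novel, chrom, start, end, strand,
#'   ambiguous, multi_gene, score).
#' @param genes_path,peptides_path Output CSV paths.
#' @return Invisibly, list of the two sorted tables.
#' @export
write_reports <- function(genes_table, peptides_table, genes_path,
                          peptides_path) {
  check_report_integrity(genes_table, peptides_table)
  g <- genes_table[order(genes_table$chromosome, genes_table$gene_start,
                         genes_table$gene_id), , drop = FALSE]
  genic <- !is.na(peptides_table$gene_id) & nzchar(peptides_table$gene_id)
  p1 <- peptides_table[genic, , drop = FALSE]
  p1 <- p1[order(p1$gene_id, p1$peptide_id), , drop = FALSE]
  p2 <- peptides_table[!genic, , drop = FALSE]
  p2 <- p2[order(p2$chrom, p2$start, p2$peptide_id), , drop = FALSE]
  p <- rbind(p1, p2)
  utils::write.csv(g, genes_path, row.names = FALSE, quote = TRUE,
                   eol = "\n", na = "")
  utils::write.csv(p, peptides_path, row.names = FALSE, quote = TRUE,
                   eol = "\n", na = "")
  invisible(list(genes = g, peptides = p))
}

check_report_integrity <- function(genes_table, peptides_table) {
  genic <- peptides_table[!is.na(peptides_table$gene_id) &
                            nzchar(peptides_table$gene_id), , drop = FALSE]
  extra <- setdiff(unique(genic$gene_id), genes_table$gene_id)
  if (length(extra)) {
    stop("peptide rows reference gene(s) absent from the genes table: ",
         paste(extra, collapse = ", "))
  }
  for (i in seq_len(nrow(genes_table))) {
    gid <- genes_table$gene_id[i]
    rows <- genic[genic$gene_id == gid, , drop = FALSE]
    ok <- genes_table$total_peptides[i] == nrow(rows) &&
      genes_table$novel_peptides[i] == sum(rows$is_novel) &&
      genes_table$n_intronic[i] ==
        sum(rows$is_novel & rows$cluster == "intronic") &&
      genes_table$n_donor[i] ==
        sum(rows$is_novel & rows$cluster == "exon_donor_spanning") &&
      genes_table$n_acceptor[i] ==
        sum(rows$is_novel & rows$cluster == "exon_acceptor_spanning")
    if (!ok) {
      stop("master-slave integrity violation for gene '", gid,
           "': gene totals do not match grouped peptide counts")
    }
  }
  invisible(TRUE)
}

#' Export the relational tables of the proteogenomic scheme
#'
#' The gene is the master entity; protein, cDNA, unspliced-mRNA and
#' peptide tables each carry \code{gene_id} as a foreign key. Referential
#' integrity is validated before writing (intergenic peptides, which have
#' no gene, are exempt).
#'
#' @param genes_table Gene master data.frame (gene_id, chromosome,
#'   gene_start, ...).
#' @param products data.frame of gene products with columns product_id,
#'   gene_id, ptype (one of protein, cdna, unspliced_mrna) and optional
#'   sequence/length columns.
#' @param peptides_table Peptide data.frame with a gene_id column.
#' @param dir Output directory; writes gene.csv, protein.csv, cdna.csv,
#'   unspliced_mrna.csv, peptide.csv.
#' @return Invisibly, the vector of written paths.
#' @export
export_relational <- function(genes_table, products, peptides_table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fk_check <- function(tab, what, allow_missing = FALSE) {
    if (!nrow(tab)) return(invisible())
    has_gene <- !is.na(tab$gene_id) & nzchar(tab$gene_id)
    if (!allow_missing && any(!has_gene)) {
      stop(what, " row ", which(!has_gene)[1L], " has no gene_id")
    }
    dangling <- has_gene & !tab$gene_id %in% genes_table$gene_id
    if (any(dangling)) {
      stop(what, " row ", which(dangling)[1L],
           " has dangling gene_id foreign key '",
           tab$gene_id[which(dangling)[1L]], "'")
    }
  }
  fk_check(products, "product")
  fk_check(peptides_table, "peptide", allow_missing = TRUE)
  paths <- c(gene = file.path(dir, "gene.csv"),
             protein = file.path(dir, "protein.csv"),
             cdna = file.path(dir, "cdna.csv"),
             unspliced_mrna = file.path(dir, "unspliced_mrna.csv"),
             peptide = file.path(dir, "peptide.csv"))
  utils::write.csv(genes_table, paths[["gene"]], row.names = FALSE,
                   eol = "\n", na = "")
  for (pt in c("protein", "cdna", "unspliced_mrna")) {
    sub <- products[products$ptype == pt, setdiff(names(products), "ptype"),
                    drop = FALSE]
    utils::write.csv(sub, paths[[pt]], row.names = FALSE, eol = "\n",
                     na = "")
  }
  utils::write.csv(peptides_table, paths[["peptide"]], row.names = FALSE,
                   eol = "\n", na = "")
  invisible(paths)
}
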