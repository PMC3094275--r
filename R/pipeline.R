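# ---------------------------------------------------------------------------
# End-to-end pipeline: filter -> ID assignment -> mapping -> novelty ->
# classification -> reports / GFF3 / relational export / figures
# ---------------------------------------------------------------------------

#' Run the proteogenomic mapping pipeline
#'
#' Peptides identified from protein/cDNA/transcript search spaces (source
#' P/C/T) are located by six-frame search against every gene's unspliced
#' genomic sequence and lifted to chromosome coordinates; genome-database
#' peptides (source G) are searched against whole chromosomes and then
#' assigned to overlapping genes, with unassigned hits flagged
#' intergenic. Each gene-mapped location is classified into a
#' genomic-context cluster, every peptide is screened for novelty against
#' the protein database, and the results are written as an updated GFF3
#' annotation, an intergenic-evidence GFF3, master-slave gene/peptide CSV
#' reports, a relational table export, gene figures, and a JSON run
#' manifest. All outputs are deterministic for fixed inputs and options.
#'
#' Peptides with no contiguous genomic hit but a protein-database match
#' (exon-exon junction peptides) are attributed to the gene owning the
#' matching protein and reported with cluster \code{known} and note
#' \code{junction}, without fabricated split coordinates.
#'
#' @param annotation GFF3 path or parsed feature data.frame.
#' @param genome Genome FASTA path or named character vector.
#' @param proteins Protein FASTA path or named character vector.
#' @param identifications Identification table path (TSV/CSV with
#'   sequence, source_db, optional score) or data.frame.
#' @param out_dir Output directory (created if needed).
#' @param il_equivalent Treat I/L as interchangeable when matching.
#' @param min_score,min_length Identification filter thresholds.
#' @param min_len_genic Minimum peptide length for per-gene searches.
#' @param min_len_genome Minimum peptide length for genome-wide searches.
#' @param figures One of "novel" (draw genes with novel features; the
#'   default), "all", or "none".
#' @param scale,palette Figure geometry and colors.
#' @param source_prefix GFF3 source-column prefix for peptide lines.
#' @return The run manifest: output paths plus summary counts (total
#'   peptides, novel peptides, genes covered, genes to be revised,
#'   intergenic peptides, per-cluster novel-feature counts).
#' @export
run_pipeline <- function(annotation, genome, proteins, identifications,
                         out_dir, il_equivalent = TRUE, min_score = 0,
                         min_length = 6L, min_len_genic = 6L,
                         min_len_genome = 7L, figures = "novel",
                         scale = 0.2, palette = DEFAULT_PALETTE,
                         source_prefix = "pgmap") {
  features <- if (is.character(annotation)) parse_gff3(annotation)
              else annotation
  genome <- if (is.character(genome) && length(genome) == 1L &&
                file.exists(genome)) read_fasta(genome, "nt") else genome
  proteins <- if (is.character(proteins) && length(proteins) == 1L &&
                  file.exists(proteins)) read_fasta(proteins, "aa")
              else proteins
  ids <- if (is.character(identifications)) {
    read_identifications(identifications)
  } else identifications

  models <- assemble_gene_models(features)
  models <- attach_sequences(models, genome)
  index <- build_gene_index(models, chromosomes = names(genome))
  tx2gene <- tx_to_gene(models)

  peptides <- filter_identifications(ids, min_score = min_score,
                                     min_length = min_length)
  peptides <- assign_peptide_ids(peptides)
  peptides$is_novel <- novelty_screen(peptides$sequence, proteins,
                                      peptides$source_db, il_equivalent)
  message(nrow(peptides), " peptide(s) after filtering; ",
          sum(peptides$is_novel), " novel")

  located <- locate_peptides(peptides, models, genome, index,
                             il_equivalent, min_len_genic, min_len_genome)
  genic <- located$genic
  intergenic <- located$intergenic
  message(nrow(genic), " gene-mapped location(s); ",
          nrow(intergenic), " intergenic location(s)")

  # classify each genic location against its gene
  calls <- lapply(seq_len(nrow(genic)), function(i) {
    gene <- models[[genic$gene_id[i]]]
    s <- max(genic$chrom_start[i], gene$start)
    e <- min(genic$chrom_end[i], gene$end)
    cl <- classify_peptide(s, e, gene)
    data.frame(cluster = cl$cluster,
               boundaries_crossed = cl$boundaries_crossed,
               junctions = paste(cl$junctions, collapse = ","),
               clipped = s != genic$chrom_start[i] ||
                 e != genic$chrom_end[i],
               stringsAsFactors = FALSE)
  })
  genic <- cbind(genic, do.call(rbind, c(calls, list(data.frame(
    cluster = character(), boundaries_crossed = integer(),
    junctions = character(), clipped = logical())))))

  peptides_table <- build_peptides_table(peptides, genic, intergenic,
                                         models, proteins, tx2gene,
                                         il_equivalent)
  genes_table <- build_genes_table(peptides_table, models)

  # peptide evidence features for the annotation update
  pep_feats <- empty_gff3()
  for (i in seq_len(nrow(genic))) {
    gene <- models[[genic$gene_id[i]]]
    parent <- if (length(gene$transcripts)) {
      names(gene$transcripts)[1L]
    } else gene$gene_id
    pep_feats <- rbind(pep_feats, peptide_to_gff3(
      genic$peptide_id[i], parent, genic$seqid[i], genic$chrom_start[i],
      genic$chrom_end[i], genic$strand[i], genic$source_db[i],
      genic$cluster[i], genic$is_novel[i], source_prefix))
  }
  updated <- update_annotation(features, pep_feats)
  inter_feats <- intergenic_gff3(intergenic, source_prefix)

  # ---- write everything -------------------------------------------------
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(
    updated_annotation = file.path(out_dir, "updated_annotation.gff3"),
    intergenic_annotation = file.path(out_dir, "intergenic_peptides.gff3"),
    genes_report = file.path(out_dir, "genes_report.csv"),
    peptides_report = file.path(out_dir, "peptides_report.csv"),
    relational_dir = file.path(out_dir, "relational"),
    figures_dir = file.path(out_dir, "figures"),
    manifest = file.path(out_dir, "manifest.json")
  )
  write_gff3(updated, paths$updated_annotation)
  write_gff3(inter_feats, paths$intergenic_annotation)
  write_reports(genes_table, peptides_table, paths$genes_report,
                paths$peptides_report)
  # the relational gene master covers every annotated gene, not only the
  # peptide-covered ones in the genes report
  rel_genes <- data.frame(
    gene_id = names(models),
    chromosome = vapply(models, `[[`, character(1L), "seqid"),
    gene_start = vapply(models, `[[`, numeric(1L), "start"),
    gene_end = vapply(models, `[[`, numeric(1L), "end"),
    strand = vapply(models, `[[`, character(1L), "strand"),
    stringsAsFactors = FALSE
  )
  rownames(rel_genes) <- NULL
  products <- build_products(models, proteins)
  export_relational(rel_genes, products, peptides_table,
                    paths$relational_dir)

  fig_genes <- switch(figures,
    none = character(),
    all = genes_table$gene_id,
    novel = genes_table$gene_id[genes_table$has_novel_features],
    stop("unknown figures option: ", figures))
  if (length(fig_genes)) {
    dir.create(paths$figures_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in fig_genes) {
      rows <- peptides_table[!is.na(peptides_table$gene_id) &
                               peptides_table$gene_id == g &
                               !is.na(peptides_table$start), , drop = FALSE]
      gcalls <- data.frame(peptide_id = rows$peptide_id,
                           start = rows$start, end = rows$end,
                           cluster = rows$cluster,
                           stringsAsFactors = FALSE)
      render_gene_figure(models[[g]], gcalls,
                         file.path(paths$figures_dir, paste0(g, ".svg")),
                         scale = scale, palette = palette)
    }
    render_gene_figure(models[[fig_genes[1L]]], NULL,
                       file.path(paths$figures_dir,
                                 paste0(fig_genes[1L], "_model.png")),
                       scale = scale, palette = palette)
  }

  dedup <- peptides_table[!duplicated(peptides_table$peptide_id), ,
                          drop = FALSE]
  novel_feature_of <- function(cl) {
    ids <- unique(peptides_table$peptide_id[
      peptides_table$is_novel & !is.na(peptides_table$cluster) &
        peptides_table$cluster == cl])
    length(ids)
  }
  manifest <- list(
    counts = list(
      total_peptides = nrow(dedup),
      novel_peptides = sum(dedup$is_novel),
      genes_covered = nrow(genes_table),
      genes_to_be_revised = sum(genes_table$has_novel_features),
      intergenic_peptides = length(unique(
        peptides_table$peptide_id[!is.na(peptides_table$cluster) &
                                    peptides_table$cluster == "intergenic"])),
      intronic_peptides = novel_feature_of("intronic"),
      donor_spanning_peptides = novel_feature_of("exon_donor_spanning"),
      acceptor_spanning_peptides = novel_feature_of("exon_acceptor_spanning")
    ),
    paths = lapply(paths, normalizePath, mustWork = FALSE)
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

tx_to_gene <- function(models) {
  out <- character()
  for (g in names(models)) {
    txs <- names(models[[g]]$transcripts)
    out[txs] <- g
    out[g] <- g
  }
  out
}

# six-frame search of every peptide against gene (P/C/T) or chromosome
# (G) targets; returns chromosome-located genic and intergenic hit tables
locate_peptides <- function(peptides, models, genome, index,
                            il_equivalent, min_len_genic,
                            min_len_genome) {
  gene_frames <- lapply(models, function(m) {
    six_frame_translate(m$unspliced_seq)
  })
  chrom_frames <- lapply(genome, six_frame_translate)

  genic_rows <- list()
  g_hits <- list()
  for (i in seq_len(nrow(peptides))) {
    p <- peptides[i, ]
    if (p$source_db %in% c("P", "C", "T")) {
      for (g in names(models)) {
        hits <- match_in_frames(p$sequence, gene_frames[[g]],
                                nchar(models[[g]]$unspliced_seq), g,
                                p$peptide_id, il_equivalent,
                                min_len_genic)
        if (nrow(hits)) {
          hits <- lift_to_chromosome(hits, models[[g]])
          hits$gene_id <- g
          genic_rows[[length(genic_rows) + 1L]] <- hits
        }
      }
    } else {
      for (chrom in names(genome)) {
        hits <- match_in_frames(p$sequence, chrom_frames[[chrom]],
                                nchar(genome[[chrom]]), chrom,
                                p$peptide_id, il_equivalent,
                                min_len_genome)
        if (nrow(hits)) {
          hits$seqid <- chrom
          hits$chrom_start <- hits$local_start
          hits$chrom_end <- hits$local_end
          hits$strand <- ifelse(startsWith(hits$frame, "F"), "+", "-")
          g_hits[[length(g_hits) + 1L]] <- hits
        }
      }
    }
  }
  genic <- do.call(rbind, c(genic_rows, list(empty_located())))
  g_all <- do.call(rbind, c(g_hits, list(empty_located_g())))
  part <- flag_intergenic(g_all, index)
  if (nrow(part$genic)) {
    genic <- rbind(genic,
                   part$genic[, c(names(empty_located())), drop = FALSE])
  }
  # a P/C/T peptide found in several genes is multi-gene
  if (nrow(genic)) {
    n_genes <- tapply(genic$gene_id, genic$peptide_id,
                      function(x) length(unique(x)))
    genic$multi_gene <- unname(n_genes[genic$peptide_id]) > 1L
  } else {
    genic$multi_gene <- logical()
  }
  # ambiguity = more than one distinct genomic location overall
  loc_key <- function(df) paste(df$seqid, df$chrom_start, df$chrom_end,
                                df$strand)
  all_locs <- rbind(
    data.frame(peptide_id = genic$peptide_id, key = loc_key(genic),
               stringsAsFactors = FALSE),
    data.frame(peptide_id = part$intergenic$peptide_id,
               key = loc_key(part$intergenic), stringsAsFactors = FALSE)
  )
  n_loc <- tapply(all_locs$key, all_locs$peptide_id,
                  function(x) length(unique(x)))
  amb <- function(ids) {
    if (!length(ids)) return(logical())
    unname(n_loc[ids]) > 1L
  }
  genic$ambiguous <- amb(genic$peptide_id)
  inter <- part$intergenic
  inter$ambiguous <- amb(inter$peptide_id)
  # carry peptide metadata onto hit rows
  meta <- peptides[match(genic$peptide_id, peptides$peptide_id), ,
                   drop = FALSE]
  genic$sequence <- meta$sequence
  genic$source_db <- meta$source_db
  genic$is_novel <- meta$is_novel
  genic$score <- if ("score" %in% names(meta)) meta$score else NA
  meta_i <- peptides[match(inter$peptide_id, peptides$peptide_id), ,
                     drop = FALSE]
  inter$sequence <- meta_i$sequence
  inter$source_db <- meta_i$source_db
  inter$is_novel <- meta_i$is_novel
  inter$score <- if ("score" %in% names(meta_i)) meta_i$score else NA
  list(genic = genic, intergenic = inter)
}

empty_located <- function() {
  cbind(empty_hits(), data.frame(
    seqid = character(), chrom_start = integer(), chrom_end = integer(),
    strand = character(), gene_id = character(), stringsAsFactors = FALSE))
}

empty_located_g <- function() {
  cbind(empty_hits(), data.frame(
    seqid = character(), chrom_start = integer(), chrom_end = integer(),
    strand = character(), stringsAsFactors = FALSE))
}

build_peptides_table <- function(peptides, genic, intergenic, models,
                                 proteins, tx2gene, il_equivalent) {
  rows <- list()
  if (nrow(genic)) {
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_id = genic$peptide_id, gene_id = genic$gene_id,
      sequence = genic$sequence, source_db = genic$source_db,
      cluster = genic$cluster, is_novel = genic$is_novel,
      chrom = genic$seqid, start = genic$chrom_start,
      end = genic$chrom_end, strand = genic$strand,
      gene_strand = vapply(genic$gene_id,
                           function(g) models[[g]]$strand, character(1L)),
      ambiguous = genic$ambiguous, multi_gene = genic$multi_gene,
      score = genic$score, note = "", stringsAsFactors = FALSE)
  }
  if (nrow(intergenic)) {
    rows[[length(rows) + 1L]] <- data.frame(
      peptide_id = intergenic$peptide_id, gene_id = NA_character_,
      sequence = intergenic$sequence, source_db = intergenic$source_db,
      cluster = "intergenic", is_novel = intergenic$is_novel,
      chrom = intergenic$seqid, start = intergenic$chrom_start,
      end = intergenic$chrom_end, strand = intergenic$strand,
      gene_strand = NA_character_, ambiguous = intergenic$ambiguous,
      multi_gene = FALSE, score = intergenic$score, note = "",
      stringsAsFactors = FALSE)
  }
  # peptides with no genomic hit at all
  hit_ids <- unique(c(genic$peptide_id, intergenic$peptide_id))
  unhit <- peptides[!peptides$peptide_id %in% hit_ids, , drop = FALSE]
  for (i in seq_len(nrow(unhit))) {
    p <- unhit[i, ]
    if (!p$is_novel) {
      # exon-exon junction peptide: matches the spliced protein but has
      # no contiguous genomic window; attribute via the protein entry
      prot_hit <- which(grepl(canon_il(p$sequence, il_equivalent),
                              canon_il(unname(proteins), il_equivalent),
                              fixed = TRUE))
      gid <- if (length(prot_hit)) {
        g <- tx2gene[names(proteins)[prot_hit[1L]]]
        if (is.na(g)) NA_character_ else unname(g)
      } else NA_character_
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = p$peptide_id, gene_id = gid, sequence = p$sequence,
        source_db = p$source_db, cluster = "known", is_novel = FALSE,
        chrom = NA_character_, start = NA_integer_, end = NA_integer_,
        strand = NA_character_, gene_strand = NA_character_,
        ambiguous = FALSE, multi_gene = FALSE,
        score = if ("score" %in% names(p)) p$score else NA,
        note = "junction", stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = p$peptide_id, gene_id = NA_character_,
        sequence = p$sequence, source_db = p$source_db,
        cluster = NA_character_, is_novel = TRUE, chrom = NA_character_,
        start = NA_integer_, end = NA_integer_, strand = NA_character_,
        gene_strand = NA_character_, ambiguous = FALSE,
        multi_gene = FALSE,
        score = if ("score" %in% names(p)) p$score else NA,
        note = "unmapped", stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide_id = character(), gene_id = character(),
                      sequence = character(), source_db = character(),
                      cluster = character(), is_novel = logical(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      gene_strand = character(), ambiguous = logical(),
                      multi_gene = logical(), score = numeric(),
                      note = character(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

build_genes_table <- function(peptides_table, models) {
  genic <- peptides_table[!is.na(peptides_table$gene_id), , drop = FALSE]
  gids <- unique(genic$gene_id)
  out <- lapply(gids, function(g) {
    s <- summarize_gene(g, genic[genic$gene_id == g, , drop = FALSE],
                        seqid = models[[g]]$seqid)
    s$gene_start <- models[[g]]$start
    s
  })
  out <- do.call(rbind, c(out, list(data.frame(
    gene_id = character(), chromosome = character(),
    total_peptides = integer(), novel_peptides = integer(),
    n_intronic = integer(), n_donor = integer(), n_acceptor = integer(),
    n_known_novel = integer(), has_novel_features = logical(),
    gene_start = integer(), stringsAsFactors = FALSE))))
  rownames(out) <- NULL
  out
}

build_products <- function(models, proteins) {
  rows <- list()
  for (g in names(models)) {
    m <- models[[g]]
    rows[[length(rows) + 1L]] <- data.frame(
      product_id = g, gene_id = g, ptype = "unspliced_mrna",
      length = m$end - m$start + 1L, stringsAsFactors = FALSE)
    for (tx in names(m$transcripts)) {
      exons <- m$transcripts[[tx]]$exons
      rows[[length(rows) + 1L]] <- data.frame(
        product_id = tx, gene_id = g, ptype = "cdna",
        length = sum(exons$end - exons$start + 1L),
        stringsAsFactors = FALSE)
      if (tx %in% names(proteins)) {
        rows[[length(rows) + 1L]] <- data.frame(
          product_id = tx, gene_id = g, ptype = "protein",
          length = nchar(proteins[[tx]]), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(rows, list(data.frame(
    product_id = character(), gene_id = character(), ptype = character(),
    length = integer(), stringsAsFactors = FALSE))))
}
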