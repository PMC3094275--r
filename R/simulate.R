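# ---------------------------------------------------------------------------
# Synthetic proteogenomics dataset generator
#
# Emulates the structure of a shotgun-proteogenomics study: an annotated
# multi-exon genome, the translated proteome, and a peptide
# identification table containing peptides cut from exonic, intronic,
# splice-boundary-spanning, intergenic and exon-junction translation
# products, each with a known class label (TruthRecord) so that every
# pipeline stage can be validated end-to-end.
# ---------------------------------------------------------------------------

SENSE_CODONS <- {
  b <- c("T", "C", "A", "G")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(cods, c("TAA", "TAG", "TGA"))
}

#' Default simulation configuration
#'
#' Study conditions for the synthetic dataset: a small multi-chromosome
#' genome of multi-exon genes on both strands with UTR-flanked CDS exons,
#' and a peptide plan covering every genomic-context class.
#'
#' @param ... Named overrides of the defaults.
#' @return A list of simulation parameters (class
#'   \code{"simulation_config"}).
#' @export
simulation_config <- function(...) {
  cfg <- list(
    n_chromosomes = 3L,
    genes_per_chromosome = 10L,
    exons_per_gene = c(2L, 6L),
    cds_exon_len = c(90L, 300L),     # per-exon CDS, rounded to codons
    utr_len = c(30L, 90L),
    intron_len = c(60L, 300L),
    intergenic_gap = c(200L, 1000L),
    p_minus_strand = 0.5,
    peptide_plan = c(known = 25L, intronic = 25L, donor = 25L,
                     acceptor = 25L, intergenic = 25L, junction = 10L),
    peptide_len = c(7L, 25L),
    score_range = c(20, 120),
    tryptic = FALSE,
    unique_peptides = TRUE,
    plant_duplicates = 0L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown simulation parameter(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  ranges <- c("exons_per_gene", "cds_exon_len", "utr_len", "intron_len",
              "intergenic_gap", "peptide_len")
  for (r in ranges) {
    if (any(cfg[[r]] <= 0) || cfg[[r]][1L] > cfg[[r]][2L]) {
      stop("invalid range for ", r)
    }
  }
  structure(cfg, class = "simulation_config")
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_int <- function(range) {
  if (range[1L] == range[2L]) return(range[1L])
  sample(range[1L]:range[2L], 1L)
}

# uniform draw from [lo, hi]; safe when lo == hi (sample(x, 1) on a
# length-one vector would draw from 1:x instead)
sample_between <- function(lo, hi) {
  if (lo >= hi) lo else sample(lo:hi, 1L)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_fwd <- function(nt) {
  translate_dna(Biostrings::DNAString(nt))
}

#' Generate a synthetic genome, annotation and proteome
#'
#' Builds each gene in transcription order as
#' UTR5 - CDS exon - intron - ... - CDS exon - UTR3, with per-exon CDS
#' lengths in whole codons drawn from stop-free sense codons (so the
#' translated proteins contain no \code{*} by construction). Minus-strand
#' genes are written into the chromosome as the reverse complement with
#' mirrored coordinates. Identical seed and configuration give identical
#' output.
#'
#' @param config A \code{simulation_config}.
#' @param seed Integer RNG seed.
#' @return list(genome, features, proteins, models, gene_recs, intergenic):
#'   named chromosome sequences, the GFF3 feature data.frame, named
#'   protein sequences, assembled gene models, the generator's internal
#'   per-gene structure records, and the intergenic intervals per
#'   chromosome.
#' @export
generate_genome <- function(config = simulation_config(), seed = 1L) {
  set.seed(seed)
  genome <- character()
  feats <- list()
  proteins <- character()
  gene_recs <- list()
  intergenic <- list()

  for (ci in seq_len(config$n_chromosomes)) {
    chrom <- sprintf("chr%02d", ci)
    seq_parts <- character()
    pos <- 0L            # length emitted so far
    gaps <- list()
    for (gi in seq_len(config$genes_per_chromosome)) {
      gap <- rand_int(config$intergenic_gap)
      seq_parts <- c(seq_parts, rand_dna(gap))
      gaps[[length(gaps) + 1L]] <- c(pos + 1L, pos + gap)
      pos <- pos + gap

      gene_id <- sprintf("SYNG%02d%03d", ci, gi)
      tx_id <- paste0(gene_id, ".1")
      strand <- if (stats::runif(1L) < config$p_minus_strand) "-" else "+"
      n_ex <- rand_int(config$exons_per_gene)
      cds_len <- vapply(seq_len(n_ex), function(i) {
        3L * (rand_int(config$cds_exon_len) %/% 3L)
      }, integer(1L))
      cds_len <- pmax(cds_len, 3L * (config$cds_exon_len[1L] %/% 3L))
      u5 <- rand_int(config$utr_len)
      u3 <- rand_int(config$utr_len)
      int_len <- if (n_ex > 1L) {
        vapply(seq_len(n_ex - 1L), function(i) rand_int(config$intron_len),
               integer(1L))
      } else integer()

      cds_nt <- vapply(cds_len, function(l) {
        paste(sample(SENSE_CODONS, l %/% 3L, replace = TRUE), collapse = "")
      }, character(1L))
      # segments in transcription order: utr5, cds1, i1, cds2, ..., utr3
      seg_seq <- c(rand_dna(u5), cds_nt[1L])
      seg_lab <- c("utr5", "cds")
      if (n_ex > 1L) {
        for (i in seq_len(n_ex - 1L)) {
          seg_seq <- c(seg_seq, rand_dna(int_len[i]), cds_nt[i + 1L])
          seg_lab <- c(seg_lab, "intron", "cds")
        }
      }
      seg_seq <- c(seg_seq, rand_dna(u3))
      seg_lab <- c(seg_lab, "utr3")
      seg_len <- nchar(seg_seq)
      construct <- paste(seg_seq, collapse = "")
      L <- nchar(construct)
      gstart <- pos + 1L
      gend <- pos + L
      genomic <- if (strand == "+") construct else revcomp(construct)
      seq_parts <- c(seq_parts, genomic)
      pos <- pos + L

      # map construct-local [a,b] (1-based) to genomic coordinates
      locmap <- function(a, b) {
        if (strand == "+") c(gstart + a - 1L, gstart + b - 1L)
        else c(gstart + (L - b), gstart + (L - a))
      }
      ends <- cumsum(seg_len)
      starts <- ends - seg_len + 1L
      seg_iv <- t(vapply(seq_along(seg_seq), function(i) {
        locmap(starts[i], ends[i])
      }, integer(2L)))
      cds_iv <- seg_iv[seg_lab == "cds", , drop = FALSE]
      intron_iv <- seg_iv[seg_lab == "intron", , drop = FALSE]
      utr5_iv <- seg_iv[seg_lab == "utr5", , drop = FALSE]
      utr3_iv <- seg_iv[seg_lab == "utr3", , drop = FALSE]
      # exons = transcribed blocks: utr5+cds1 merged, internal cds,
      # cdsn+utr3 merged (contiguity holds by construction)
      exon_loc <- cbind(
        c(starts[1L], starts[seg_lab == "cds"][-1L]),
        c(ends[seg_lab == "cds"][-sum(seg_lab == "cds")], ends[length(ends)])
      )
      if (n_ex == 1L) exon_loc <- cbind(starts[1L], ends[length(ends)])
      exon_iv <- t(apply(exon_loc, 1L, function(ab) locmap(ab[1L], ab[2L])))

      protein <- translate_fwd(paste(cds_nt, collapse = ""))
      proteins[[tx_id]] <- protein

      sort_iv <- function(m) m[order(m[, 1L]), , drop = FALSE]
      exon_iv <- sort_iv(exon_iv); cds_iv <- sort_iv(cds_iv)
      intron_iv <- sort_iv(intron_iv)

      frow <- function(type, iv, id = NA, parent = NA, phase = ".") {
        data.frame(seqid = chrom, source = "pgsim", type = type,
                   start = iv[1L], end = iv[2L], score = ".",
                   strand = strand, phase = phase,
                   attributes = gff3_attributes(id = id, parent = parent),
                   stringsAsFactors = FALSE)
      }
      rows <- list(frow("gene", c(gstart, gend), id = gene_id),
                   frow("mRNA", c(gstart, gend), id = tx_id,
                        parent = gene_id))
      for (i in seq_len(nrow(exon_iv))) {
        rows[[length(rows) + 1L]] <- frow("exon", exon_iv[i, ],
                                          parent = tx_id)
      }
      for (i in seq_len(nrow(cds_iv))) {
        rows[[length(rows) + 1L]] <- frow("CDS", cds_iv[i, ],
                                          parent = tx_id, phase = "0")
      }
      rows[[length(rows) + 1L]] <- frow("five_prime_UTR", utr5_iv[1L, ],
                                        parent = tx_id)
      rows[[length(rows) + 1L]] <- frow("three_prime_UTR", utr3_iv[1L, ],
                                        parent = tx_id)
      feats[[length(feats) + 1L]] <- do.call(rbind, rows)

      gene_recs[[gene_id]] <- list(
        gene_id = gene_id, tx_id = tx_id, seqid = chrom, strand = strand,
        start = gstart, end = gend,
        exons = data.frame(start = exon_iv[, 1L], end = exon_iv[, 2L]),
        cds = data.frame(start = cds_iv[, 1L], end = cds_iv[, 2L]),
        introns = data.frame(start = intron_iv[, 1L],
                             end = intron_iv[, 2L]),
        cds_len = cds_len, protein = protein
      )
    }
    gap <- rand_int(config$intergenic_gap)
    seq_parts <- c(seq_parts, rand_dna(gap))
    gaps[[length(gaps) + 1L]] <- c(pos + 1L, pos + gap)
    genome[[chrom]] <- paste(seq_parts, collapse = "")
    intergenic[[chrom]] <- do.call(rbind, gaps)
  }

  features <- do.call(rbind, feats)
  features$feature_id <- gff3_attr(features$attributes, "ID")
  features$parent <- gff3_attr(features$attributes, "Parent")
  attr(features, "gff_version") <- "3"
  models <- assemble_gene_models(features)
  list(genome = genome, features = features, proteins = proteins,
       models = models, gene_recs = gene_recs, intergenic = intergenic)
}

# junction left-base coordinates of a generated gene, by splice-site type
rec_junctions <- function(rec) {
  E <- rec$exons
  n <- nrow(E)
  if (n < 2L) return(list(donor = integer(), acceptor = integer()))
  right_of_exon <- E$end[-n]        # boundary exon_end | intron_start
  left_of_exon <- E$start[-1L] - 1L # boundary intron_end | exon_start
  if (rec$strand == "+") {
    list(donor = right_of_exon, acceptor = left_of_exon)
  } else {
    list(donor = left_of_exon, acceptor = right_of_exon)
  }
}

# translate a genomic window in the gene's transcription orientation
window_peptide <- function(chrom_seq, s, e, strand) {
  slice <- substr(chrom_seq, s, e)
  translate_fwd(if (strand == "-") revcomp(slice) else slice)
}

#' Plant class-labelled peptides into a synthetic dataset
#'
#' For each requested class the peptide is cut from the appropriate
#' translation product: known = in-frame window of one CDS exon; intronic
#' = stop-free window inside an intron; donor/acceptor = window
#' straddling the respective splice junction of a retained-intron
#' conceptual translation; intergenic = stop-free window of an intergenic
#' region; junction = substring of the spliced protein crossing an
#' exon-exon join (no contiguous genomic match). Every truth interval is
#' verified by re-translation before emission, and peptides are made
#' genome-unique by rejection sampling unless \code{unique_peptides} is
#' disabled. \code{plant_duplicates > 0} additionally copies the coding
#' sequence of that many known peptides into intergenic gaps (modifying
#' the genome) to create deliberately ambiguous multi-hit peptides.
#'
#' @param sim Output of \code{generate_genome}.
#' @param config The \code{simulation_config} used to generate it.
#' @param seed Integer RNG seed.
#' @return list(identifications, truth, genome): the identification
#'   table (sequence, source_db, score), the truth records (peptide_id
#'   order matches the table) and the possibly-modified genome.
#' @export
plant_peptides <- function(sim, config = simulation_config(), seed = 2L) {
  set.seed(seed)
  plan <- config$peptide_plan
  recs <- sim$gene_recs
  genome <- sim$genome
  proteins_canon <- canon_il(unname(sim$proteins))
  frames <- lapply(genome, function(s) canon_il(six_frame_translate(s)))
  count_hits <- function(pep) {
    p <- canon_il(pep)
    sum(vapply(frames, function(fr) {
      sum(vapply(fr, function(aa) {
        m <- gregexpr(p, aa, fixed = TRUE)[[1L]]
        if (m[1L] == -1L) 0L else length(m)
      }, integer(1L)))
    }, integer(1L)))
  }
  in_protein <- function(pep) any(grepl(canon_il(pep), proteins_canon,
                                        fixed = TRUE))
  ok_pep <- function(pep) {
    !grepl("[X*]", pep) &&
      (!config$tryptic || grepl("[KR]$", pep))
  }

  truth <- list()
  max_try <- 500L
  for (cls in names(plan)) {
    for (k in seq_len(plan[[cls]])) {
      placed <- FALSE
      for (tr in seq_len(max_try)) {
        L <- rand_int(config$peptide_len)
        w <- 3L * L
        rec <- recs[[sample(names(recs), 1L)]]
        cand <- NULL
        if (cls == "known") {
          ex <- sample(nrow(rec$cds), 1L)
          cs <- rec$cds$start[ex]; ce <- rec$cds$end[ex]
          nslots <- (ce - cs + 1L - w) %/% 3L
          if (nslots < 0L) next
          k3 <- 3L * sample_between(0L, nslots)
          iv <- if (rec$strand == "+") c(cs + k3, cs + k3 + w - 1L)
                else c(ce - k3 - w + 1L, ce - k3)
          cand <- list(iv = iv, src = "P")
        } else if (cls == "intronic") {
          if (!nrow(rec$introns)) next
          it <- sample(nrow(rec$introns), 1L)
          is0 <- rec$introns$start[it]; ie0 <- rec$introns$end[it]
          if (ie0 - is0 + 1L < w) next
          p0 <- sample_between(is0, ie0 - w + 1L)
          cand <- list(iv = c(p0, p0 + w - 1L),
                       src = sample(c("C", "T"), 1L))
        } else if (cls %in% c("donor", "acceptor")) {
          jn <- rec_junctions(rec)[[cls]]
          if (!length(jn)) next
          b <- jn[sample(length(jn), 1L)]
          all_b <- sort(unlist(rec_junctions(rec), use.names = FALSE))
          prev_b <- max(c(rec$start - 1L, all_b[all_b < b]))
          next_b <- min(c(rec$end, all_b[all_b > b]))
          lo <- max(prev_b + 1L, b - w + 2L)
          hi <- min(b, next_b - w + 1L)
          if (lo > hi) next
          p0 <- sample_between(lo, hi)
          cand <- list(iv = c(p0, p0 + w - 1L),
                       src = sample(c("C", "T"), 1L))
        } else if (cls == "intergenic") {
          chrom <- sample(names(genome), 1L)
          gaps <- sim$intergenic[[chrom]]
          gp <- gaps[sample(nrow(gaps), 1L), ]
          if (gp[2L] - gp[1L] + 1L < w) next
          p0 <- sample_between(gp[1L], gp[2L] - w + 1L)
          strand <- sample(c("+", "-"), 1L)
          pep <- window_peptide(genome[[chrom]], p0, p0 + w - 1L, strand)
          if (!ok_pep(pep) || in_protein(pep)) next
          if (config$unique_peptides && count_hits(pep) != 1L) next
          truth[[length(truth) + 1L]] <- data.frame(
            sequence = pep, class = cls, gene_id = NA_character_,
            seqid = chrom, start = p0, end = p0 + w - 1L,
            strand = strand, source_db = "G", stringsAsFactors = FALSE)
          placed <- TRUE
          break
        } else if (cls == "junction") {
          breaks <- cumsum(rec$cds_len %/% 3L)
          breaks <- breaks[-length(breaks)]
          if (!length(breaks)) next
          A <- breaks[sample(length(breaks), 1L)]
          lo <- max(1L, A - L + 3L)
          hi <- min(A - 1L, nchar(rec$protein) - L + 1L)
          if (lo > hi) next
          a0 <- sample_between(lo, hi)
          pep <- substr(rec$protein, a0, a0 + L - 1L)
          if (!ok_pep(pep)) next
          if (count_hits(pep) != 0L) next
          truth[[length(truth) + 1L]] <- data.frame(
            sequence = pep, class = cls, gene_id = rec$gene_id,
            seqid = rec$seqid, start = NA_integer_, end = NA_integer_,
            strand = rec$strand, source_db = "C",
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (is.null(cand)) next
        pep <- window_peptide(genome[[rec$seqid]], cand$iv[1L],
                              cand$iv[2L], rec$strand)
        if (!ok_pep(pep)) next
        if (cls == "known" && !in_protein(pep)) next
        if (cls != "known" && in_protein(pep)) next
        if (config$unique_peptides && count_hits(pep) != 1L) next
        truth[[length(truth) + 1L]] <- data.frame(
          sequence = pep, class = cls, gene_id = rec$gene_id,
          seqid = rec$seqid, start = cand$iv[1L], end = cand$iv[2L],
          strand = rec$strand, source_db = cand$src,
          stringsAsFactors = FALSE)
        placed <- TRUE
        break
      }
      if (!placed) {
        stop("could not place a '", cls, "' peptide after ", max_try,
             " attempts; configuration may be infeasible")
      }
    }
  }
  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL

  # deliberately ambiguous peptides: copy the coding slice of a known
  # peptide into the intron of a different gene, so the peptide also
  # matches there (peptides from protein/cDNA/transcript searches are
  # located per gene, so the second copy must lie inside a gene span)
  n_dup <- min(config$plant_duplicates, sum(truth$class == "known"))
  if (n_dup > 0L) {
    known_idx <- which(truth$class == "known")[seq_len(n_dup)]
    for (i in known_idx) {
      tr <- truth[i, ]
      slice <- substr(genome[[tr$seqid]], tr$start, tr$end)
      hosts <- setdiff(names(recs), tr$gene_id)
      for (tr2 in seq_len(100L)) {
        host <- recs[[sample(hosts, 1L)]]
        if (!nrow(host$introns)) next
        it <- sample(nrow(host$introns), 1L)
        is0 <- host$introns$start[it]; ie0 <- host$introns$end[it]
        if (ie0 - is0 + 1L < nchar(slice) + 6L) next
        at <- is0 + 3L
        # never overwrite another planted peptide's truth interval
        clash <- !is.na(truth$start) & truth$seqid == host$seqid &
          truth$start <= at + nchar(slice) - 1L & truth$end >= at
        if (any(clash)) next
        substr(genome[[host$seqid]], at, at + nchar(slice) - 1L) <- slice
        break
      }
    }
  }

  # sanity: every truth interval re-translates to its peptide
  with_iv <- which(!is.na(truth$start))
  for (i in with_iv) {
    pep <- window_peptide(genome[[truth$seqid[i]]], truth$start[i],
                          truth$end[i], truth$strand[i])
    if (canon_il(pep) != canon_il(truth$sequence[i])) {
      stop("internal error: truth interval does not re-translate to its ",
           "peptide (row ", i, ")")
    }
  }

  identifications <- data.frame(
    sequence = truth$sequence,
    source_db = truth$source_db,
    score = round(stats::runif(nrow(truth), config$score_range[1L],
                               config$score_range[2L]), 2L),
    stringsAsFactors = FALSE
  )
  list(identifications = identifications, truth = truth, genome = genome)
}

#' Generate a complete synthetic dataset
#'
#' Runs \code{generate_genome} then \code{plant_peptides} with seeds
#' derived from one master seed.
#'
#' @param config A \code{simulation_config}.
#' @param seed Integer master seed.
#' @return list(genome, features, proteins, models, gene_recs,
#'   intergenic, identifications, truth).
#' @export
simulate_dataset <- function(config = simulation_config(), seed = 1L) {
  sim <- generate_genome(config, seed = seed)
  planted <- plant_peptides(sim, config, seed = seed + 104729L)
  sim$genome <- planted$genome
  sim$identifications <- planted$identifications
  sim$truth <- planted$truth
  sim
}

#' Write a synthetic dataset to standard files
#'
#' @param sim Output of \code{simulate_dataset}.
#' @param dir Output directory; writes genome.fasta, annotation.gff3,
#'   proteins.fasta, identifications.tsv and truth.tsv.
#' @return Invisibly, the named vector of written paths.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fasta"),
             annotation = file.path(dir, "annotation.gff3"),
             proteins = file.path(dir, "proteins.fasta"),
             identifications = file.path(dir, "identifications.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_fasta(sim$genome, paths[["genome"]])
  write_gff3(sim$features, paths[["annotation"]])
  write_fasta(sim$proteins, paths[["proteins"]])
  utils::write.table(sim$identifications, paths[["identifications"]],
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(paths)
}
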