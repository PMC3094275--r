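# ---------------------------------------------------------------------------
# GFF3 parsing and writing
#
# Features are kept as a plain data.frame with one row per feature line and
# the nine GFF3 columns stored verbatim (score and phase as character, so
# that serialization is byte-faithful). Attribute strings are kept raw;
# individual tags are pulled out on demand with gff3_attr().
# ---------------------------------------------------------------------------

GFF3_COLUMNS <- c("seqid", "source", "type", "start", "end",
                  "score", "strand", "phase", "attributes")

#' Parse a GFF3 annotation file
#'
#' Reads a 9-column GFF3 file into a data.frame, one row per feature line.
#' Coordinates are 1-based fully-closed, as in the file. Comment and
#' directive lines are skipped; a \code{##gff-version} directive, when
#' present, is recorded in the \code{"gff_version"} attribute of the result.
#' Score and phase are kept as character so that a parse/write round trip
#' reproduces feature lines byte-identically.
#'
#' @param path Path to a GFF3 file, or a character vector of GFF3 lines
#'   (auto-detected: any element containing a tab is treated as content).
#' @return A data.frame with columns seqid, source, type, start, end, score,
#'   strand, phase, attributes, feature_id, parent. \code{feature_id} and
#'   \code{parent} are the ID/Parent attribute tags (NA when absent).
#' @export
parse_gff3 <- function(path) {
  lines <- if (length(path) == 1L && !grepl("\t|\n", path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE), use.names = FALSE)
  }
  gff_version <- NA_character_
  ver <- grep("^##gff-version", lines, value = TRUE)
  if (length(ver)) gff_version <- sub("^##gff-version\\s*", "", ver[1L])

  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) {
    out <- empty_gff3()
    attr(out, "gff_version") <- gff_version
    return(out)
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  ncol_ok <- lengths(fields) == 9L
  if (any(!ncol_ok)) {
    bad <- idx[which(!ncol_ok)[1L]]
    stop("GFF3 parse error at line ", bad, ": expected 9 tab-separated ",
         "columns, found ", lengths(fields)[which(!ncol_ok)[1L]])
  }
  m <- matrix(unlist(fields, use.names = FALSE), ncol = 9L, byrow = TRUE)
  start <- suppressWarnings(as.integer(m[, 4L]))
  end <- suppressWarnings(as.integer(m[, 5L]))
  bad_coord <- is.na(start) | is.na(end)
  if (any(bad_coord)) {
    stop("GFF3 parse error at line ", idx[which(bad_coord)[1L]],
         ": non-integer coordinates")
  }
  rev_coord <- start > end
  if (any(rev_coord)) {
    stop("GFF3 parse error at line ", idx[which(rev_coord)[1L]],
         ": start > end (", start[which(rev_coord)[1L]], " > ",
         end[which(rev_coord)[1L]], ")")
  }
  out <- data.frame(
    seqid = m[, 1L], source = m[, 2L], type = m[, 3L],
    start = start, end = end, score = m[, 6L], strand = m[, 7L],
    phase = m[, 8L], attributes = m[, 9L],
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$type))) {
    stop("GFF3 parse error at line ", idx[which(!nzchar(out$type))[1L]],
         ": empty feature type")
  }
  out$feature_id <- gff3_attr(out$attributes, "ID")
  out$parent <- gff3_attr(out$attributes, "Parent")
  attr(out, "gff_version") <- gff_version
  out
}

empty_gff3 <- function() {
  data.frame(seqid = character(), source = character(), type = character(),
             start = integer(), end = integer(), score = character(),
             strand = character(), phase = character(),
             attributes = character(), feature_id = character(),
             parent = character(), stringsAsFactors = FALSE)
}

#' Extract an attribute tag from GFF3 attribute strings
#'
#' @param attributes Character vector of raw column-9 attribute strings.
#' @param key Tag name, e.g. \code{"ID"} or \code{"Parent"}.
#' @return Character vector of values (NA where the tag is absent).
#' @export
gff3_attr <- function(attributes, key) {
  pat <- paste0("(^|;)\\s*", key, "=([^;]*)")
  m <- regexpr(pat, attributes, perl = TRUE)
  out <- rep(NA_character_, length(attributes))
  hit <- m != -1L
  if (any(hit)) {
    out[hit] <- sub(pat, "\\2", regmatches(attributes, m), perl = TRUE)
  }
  out
}

#' Build a GFF3 attribute string
#'
#' Serializes tags with ID first, Parent second, then the remaining tags in
#' the order given.
#'
#' @param id Feature ID (or NA to omit).
#' @param parent Parent feature ID (or NA to omit).
#' @param ... Further named tags (coerced to character).
#' @return A single attribute string.
#' @export
gff3_attributes <- function(id = NA, parent = NA, ...) {
  extra <- list(...)
  parts <- character()
  if (!is.na(id)) parts <- c(parts, paste0("ID=", id))
  if (!is.na(parent)) parts <- c(parts, paste0("Parent=", parent))
  if (length(extra)) {
    parts <- c(parts, paste0(names(extra), "=",
                             vapply(extra, as.character, character(1L))))
  }
  paste(parts, collapse = ";")
}

#' Serialize features to GFF3
#'
#' Emits a \code{##gff-version 3} directive followed by one tab-separated
#' line per feature row. Round-trips losslessly with \code{parse_gff3} on
#' all nine columns.
#'
#' @param features A feature data.frame as returned by \code{parse_gff3}.
#' @param path Optional output path; when NULL the lines are returned.
#' @return Invisibly (or visibly when \code{path} is NULL), the GFF3 lines.
#' @export
write_gff3 <- function(features, path = NULL) {
  if (nrow(features)) {
    if (any(!nzchar(features$seqid)) || any(is.na(features$seqid))) {
      stop("cannot serialize feature without seqid")
    }
    if (any(!nzchar(features$type)) || any(is.na(features$type))) {
      stop("cannot serialize feature without type")
    }
  }
  lines <- c("##gff-version 3", gff3_feature_lines(features))
  if (is.null(path)) return(lines)
  writeLines(lines, path, sep = "\n")
  invisible(lines)
}

gff3_feature_lines <- function(features) {
  if (!nrow(features)) return(character())
  score <- as.character(features$score)
  score[is.na(score) | !nzchar(score)] <- "."
  phase <- as.character(features$phase)
  phase[is.na(phase) | !nzchar(phase)] <- "."
  paste(features$seqid, features$source, features$type,
        features$start, features$end, score, features$strand,
        phase, features$attributes, sep = "\t")
}

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

IUPAC_NT <- strsplit("ACGTURYSWKMBDHVN-.", "")[[1L]]
IUPAC_AA <- strsplit("ACDEFGHIKLMNPQRSTVWYBXZJUO*-.", "")[[1L]]

#' Read a FASTA file
#'
#' Identifiers are the first whitespace-delimited token of each header;
#' sequences are uppercased. Duplicate identifiers are an error; characters
#' outside the IUPAC alphabet produce a warning naming the first offending
#' record and position.
#'
#' @param path Path to a FASTA file.
#' @param alphabet One of "auto", "nt", "aa"; controls which IUPAC alphabet
#'   the content check uses ("auto" accepts the union).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path, alphabet = c("auto", "nt", "aa")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1L), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA identifier: ", ids[duplicated(ids)][1L])
  }
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  allowed <- switch(alphabet, nt = IUPAC_NT, aa = IUPAC_AA,
                    auto = union(IUPAC_NT, IUPAC_AA))
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1L]]
    bad <- which(!chars %in% allowed)
    if (length(bad)) {
      warning("sequence '", ids[i], "' contains non-IUPAC character '",
              chars[bad[1L]], "' at position ", bad[1L])
      break
    }
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Gene models
# ---------------------------------------------------------------------------

EXON_LEVEL_TYPES <- c("exon", "CDS", "five_prime_UTR", "three_prime_UTR",
                      "3'UTR", "5'UTR", "3'-UTR", "5'-UTR")

#' Assemble hierarchical gene models from parsed GFF3 features
#'
#' Groups transcripts under their genes via ID/Parent chains, sorts exons,
#' and derives per-transcript introns (the complement of the exons within
#' the transcript's exon span) as well as the gene-level exon union across
#' transcripts and the gene-level introns (complement of the union within
#' the gene's exon span). Exon-level features parented directly on a gene
#' are attached to an implicit transcript named after the gene. Features
#' whose Parent cannot be resolved are collected into the
#' \code{"orphans"} attribute of the result, not silently dropped.
#'
#' Unknown strand (\code{"."} or \code{"?"}) is treated as \code{"+"} with
#' a warning, so degenerate records do not abort a batch.
#'
#' @param features Feature data.frame from \code{parse_gff3}.
#' @return A named list of gene models (class \code{"gene_model_set"});
#'   each element is a list with gene_id, seqid, start, end, strand,
#'   transcripts (each with exons/cds/utr5/utr3/introns data.frames),
#'   exon_union, introns (gene level) and unspliced_seq (NULL until
#'   attached).
#' @export
assemble_gene_models <- function(features) {
  genes <- features[features$type == "gene", , drop = FALSE]
  models <- vector("list", nrow(genes))
  names(models) <- genes$feature_id
  resolved <- rep(FALSE, nrow(features))
  resolved[features$type == "gene"] <- TRUE

  if (any(genes$strand %in% c(".", "?"))) {
    warning("gene(s) with unknown strand treated as '+': ",
            paste(genes$feature_id[genes$strand %in% c(".", "?")],
                  collapse = ", "))
  }

  tx_rows <- which(!is.na(features$parent) &
                   features$parent %in% genes$feature_id &
                   !features$type %in% EXON_LEVEL_TYPES &
                   features$type != "gene")
  tx_ids <- features$feature_id[tx_rows]
  resolved[tx_rows] <- TRUE
  tx_parent <- stats::setNames(features$parent[tx_rows], tx_ids)

  child_rows <- which(features$type %in% EXON_LEVEL_TYPES)
  for (gi in seq_len(nrow(genes))) {
    g <- genes[gi, ]
    strand <- if (g$strand %in% c("+", "-")) g$strand else "+"
    own_tx <- tx_ids[tx_parent == g$feature_id]
    transcripts <- list()
    for (tid in c(own_tx, g$feature_id)) {
      rows <- child_rows[!is.na(features$parent[child_rows]) &
                         features$parent[child_rows] == tid]
      resolved[rows] <- TRUE
      if (tid == g$feature_id && !length(rows)) next
      ch <- features[rows, , drop = FALSE]
      exons <- ch[ch$type == "exon", c("start", "end"), drop = FALSE]
      if (!nrow(exons)) {
        # CDS-only transcripts: CDS segments stand in for exons
        exons <- ch[ch$type == "CDS", c("start", "end"), drop = FALSE]
      }
      exons <- exons[order(exons$start), , drop = FALSE]
      rownames(exons) <- NULL
      if (nrow(exons) > 1L &&
          any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
        stop("overlapping exons in transcript '", tid, "'")
      }
      if (nrow(exons) &&
          (min(exons$start) < g$start || max(exons$end) > g$end)) {
        stop("exon outside gene span in transcript '", tid, "'")
      }
      utr5 <- ch[ch$type %in% c("five_prime_UTR", "5'UTR", "5'-UTR"),
                 c("start", "end"), drop = FALSE]
      utr3 <- ch[ch$type %in% c("three_prime_UTR", "3'UTR", "3'-UTR"),
                 c("start", "end"), drop = FALSE]
      cds <- ch[ch$type == "CDS", c("start", "end"), drop = FALSE]
      cds <- cds[order(cds$start), , drop = FALSE]
      rownames(cds) <- rownames(utr5) <- rownames(utr3) <- NULL
      transcripts[[tid]] <- list(
        tx_id = tid, exons = exons, cds = cds, utr5 = utr5, utr3 = utr3,
        introns = interval_gaps(exons)
      )
    }
    all_exons <- do.call(rbind, c(
      lapply(transcripts, `[[`, "exons"),
      list(data.frame(start = integer(), end = integer()))
    ))
    exon_union <- reduce_intervals(all_exons)
    models[[g$feature_id]] <- structure(list(
      gene_id = g$feature_id, seqid = g$seqid,
      start = g$start, end = g$end, strand = strand,
      transcripts = transcripts,
      exon_union = exon_union,
      introns = interval_gaps(exon_union),
      unspliced_seq = NULL
    ), class = "gene_model")
  }
  orphan_rows <- which(!resolved & !is.na(features$parent))
  out <- structure(models, class = "gene_model_set")
  attr(out, "orphans") <- features[orphan_rows, , drop = FALSE]
  out
}

# gaps between consecutive sorted non-overlapping intervals
interval_gaps <- function(iv) {
  if (nrow(iv) < 2L) {
    return(data.frame(start = integer(), end = integer()))
  }
  iv <- iv[order(iv$start), , drop = FALSE]
  data.frame(start = iv$end[-nrow(iv)] + 1L, end = iv$start[-1L] - 1L)
}

reduce_intervals <- function(iv) {
  if (!nrow(iv)) return(data.frame(start = integer(), end = integer()))
  r <- IRanges::reduce(IRanges::IRanges(iv$start, iv$end))
  data.frame(start = IRanges::start(r), end = IRanges::end(r))
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model> ", x$gene_id, "  ", x$seqid, ":", x$start, "-", x$end,
      " (", x$strand, ")  ", length(x$transcripts), " transcript(s), ",
      nrow(x$exon_union), " exon block(s), ", nrow(x$introns),
      " intron(s)\n", sep = "")
  invisible(x)
}

#' @export
print.gene_model_set <- function(x, ...) {
  cat("<gene_model_set> of", length(x), "gene(s)\n")
  orphans <- attr(x, "orphans")
  if (!is.null(orphans) && nrow(orphans)) {
    cat("  ", nrow(orphans), "orphan feature(s) with unresolved Parent\n")
  }
  invisible(x)
}

#' Extract a gene's unspliced genomic sequence
#'
#' Returns the forward-strand chromosome slice spanning the gene. The
#' returned sequence is always the forward strand, for minus-strand genes
#' too; strand is handled downstream by the six-frame search.
#'
#' @param gene A gene model.
#' @param chromosome_seq The chromosome nucleotide sequence (character).
#' @return Nucleotide sequence of the gene's span.
#' @export
extract_unspliced_sequence <- function(gene, chromosome_seq) {
  if (gene$start < 1L || gene$end > nchar(chromosome_seq)) {
    stop("gene '", gene$gene_id, "' span [", gene$start, ",", gene$end,
         "] exceeds chromosome length ", nchar(chromosome_seq))
  }
  substr(chromosome_seq, gene$start, gene$end)
}

#' Attach unspliced sequences to every gene model
#'
#' @param models A gene_model_set.
#' @param genome Named character vector of chromosome sequences.
#' @return The gene_model_set with unspliced_seq populated.
#' @export
attach_sequences <- function(models, genome) {
  for (gid in names(models)) {
    chrom <- models[[gid]]$seqid
    if (!chrom %in% names(genome)) {
      stop("chromosome '", chrom, "' for gene '", gid,
           "' not present in genome")
    }
    models[[gid]]$unspliced_seq <-
      extract_unspliced_sequence(models[[gid]], genome[[chrom]])
  }
  models
}
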