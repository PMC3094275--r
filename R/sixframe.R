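# ---------------------------------------------------------------------------
# Six-frame translation search
#
# MS-identified peptides must match their source translation exactly, so
# coordinate recovery is done by exact substring search over all six
# conceptual reading frames rather than by heuristic alignment. This makes
# the mapping deterministic and exhaustive: every occurrence in every frame
# is reported.
# ---------------------------------------------------------------------------

FRAME_NAMES <- c("F1", "F2", "F3", "R1", "R2", "R3")
AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWYX", "")[[1L]]

# standard-code translation; the fuzzy-codon path (N -> X) is taken only
# when needed, as it is far more expensive per call
translate_dna <- function(dna) {
  if (Biostrings::alphabetFrequency(dna, baseOnly = TRUE)[["other"]] ||
      Biostrings::alphabetFrequency(dna)[["N"]]) {
    as.character(Biostrings::translate(dna, if.fuzzy.codon = "X",
                                       no.init.codon = TRUE))
  } else {
    as.character(Biostrings::translate(dna, no.init.codon = TRUE))
  }
}

#' Six-frame conceptual translation
#'
#' Translates a nucleotide sequence in the three forward frames (offsets
#' 0..2 of the forward strand: F1..F3) and the three reverse frames
#' (offsets 0..2 of the reverse complement: R1..R3) under the standard
#' genetic code. Trailing partial codons are dropped, codons containing N
#' translate to X, and stop codons are rendered \code{*}.
#'
#' @param nt_seq Nucleotide sequence (character, A/C/G/T/N).
#' @return Named character vector of the six frame translations.
#' @export
six_frame_translate <- function(nt_seq) {
  frames <- stats::setNames(rep("", 6L), FRAME_NAMES)
  n <- nchar(nt_seq)
  if (n < 3L) return(frames)
  fwd <- Biostrings::DNAString(nt_seq)
  rev <- Biostrings::reverseComplement(fwd)
  for (f in 0:2) {
    w <- 3L * ((n - f) %/% 3L)
    if (w >= 3L) {
      frames[[paste0("F", f + 1L)]] <-
        translate_dna(Biostrings::subseq(fwd, start = f + 1L, width = w))
      frames[[paste0("R", f + 1L)]] <-
        translate_dna(Biostrings::subseq(rev, start = f + 1L, width = w))
    }
  }
  frames
}

# I and L are isobaric and indistinguishable by MS/MS; canonicalize I -> L
# on both sides of a comparison when I/L equivalence is on.
canon_il <- function(x, il_equivalent = TRUE) {
  if (il_equivalent) chartr("I", "L", x) else x
}

#' Locate a peptide on a nucleotide target by six-frame search
#'
#' Reports every exact occurrence of the peptide in every reading frame of
#' the target. Local nucleotide coordinates are 1-based on the forward
#' strand of the target, so a reverse-frame hit at amino-acid offset a in
#' frame Rk of a length-N target occupies
#' \code{[N - (k-1) - 3a - 3L + 1, N - (k-1) - 3a]} for a peptide of L
#' residues. Matches never span a stop codon (the peptide alphabet has no
#' \code{*}). Zero hits is a valid outcome.
#'
#' @param sequence Peptide amino-acid sequence (uppercase).
#' @param target_id Identifier of the target sequence.
#' @param target_seq Target nucleotide sequence (character).
#' @param peptide_id Optional peptide identifier carried into the hits.
#' @param il_equivalent Treat I and L as interchangeable (default TRUE).
#' @param min_length Minimum peptide length searched; shorter peptides
#'   return zero hits.
#' @return data.frame with columns peptide_id, target_id, frame, aa_offset,
#'   local_start, local_end.
#' @export
find_peptide_matches <- function(sequence, target_id, target_seq,
                                 peptide_id = NA_character_,
                                 il_equivalent = TRUE, min_length = 6L) {
  chars <- strsplit(sequence, "")[[1L]]
  if (!length(chars) || any(!chars %in% AA_ALPHABET)) {
    stop("peptide sequence contains non-amino-acid characters: ",
         sequence)
  }
  frames <- six_frame_translate(target_seq)
  match_in_frames(sequence, frames, nchar(target_seq), target_id,
                  peptide_id, il_equivalent, min_length)
}

# core matcher against precomputed frame translations (reused by the
# pipeline, which translates each target once for many peptides)
match_in_frames <- function(sequence, frames, target_len, target_id,
                            peptide_id, il_equivalent, min_length) {
  out <- empty_hits()
  L <- nchar(sequence)
  if (L < min_length) return(out)
  pep <- canon_il(sequence, il_equivalent)
  for (fr in FRAME_NAMES) {
    aa <- canon_il(frames[[fr]], il_equivalent)
    if (!nzchar(aa)) next
    pos <- gregexpr(pep, aa, fixed = TRUE)[[1L]]
    if (pos[1L] == -1L) next
    a <- as.integer(pos) - 1L
    f <- as.integer(substr(fr, 2L, 2L)) - 1L
    if (startsWith(fr, "F")) {
      ls <- f + 3L * a + 1L
      le <- ls + 3L * L - 1L
    } else {
      ls <- target_len - (f + 3L * a + 3L * L) + 1L
      le <- target_len - f - 3L * a
    }
    out <- rbind(out, data.frame(
      peptide_id = peptide_id, target_id = target_id, frame = fr,
      aa_offset = a, local_start = ls, local_end = le,
      stringsAsFactors = FALSE
    ))
  }
  out
}

empty_hits <- function() {
  data.frame(peptide_id = character(), target_id = character(),
             frame = character(), aa_offset = integer(),
             local_start = integer(), local_end = integer(),
             stringsAsFactors = FALSE)
}

#' Lift gene-local hit coordinates to chromosome coordinates
#'
#' The gene's unspliced sequence is the forward-strand chromosome slice of
#' its span, so lifting is pure offset arithmetic:
#' \code{chrom = gene_start + local - 1}. The hit strand is \code{+} when a
#' forward frame lands on a plus-strand gene or a reverse frame on a
#' minus-strand gene, otherwise \code{-}.
#'
#' @param hits Hit data.frame with local coordinates (target_id must equal
#'   the gene's gene_id).
#' @param gene The gene model the hits were found on.
#' @return The hits with added columns seqid, chrom_start, chrom_end,
#'   strand.
#' @export
lift_to_chromosome <- function(hits, gene) {
  if (nrow(hits) && any(hits$target_id != gene$gene_id)) {
    stop("hits target '", hits$target_id[hits$target_id != gene$gene_id][1L],
         "' does not match gene '", gene$gene_id, "'")
  }
  hits$seqid <- rep(gene$seqid, nrow(hits))
  hits$chrom_start <- gene$start + hits$local_start - 1L
  hits$chrom_end <- gene$start + hits$local_end - 1L
  forward <- startsWith(hits$frame, "F")
  hits$strand <- ifelse(forward == (gene$strand == "+"), "+", "-")
  if (nrow(hits) &&
      (any(hits$chrom_start < gene$start) || any(hits$chrom_end > gene$end))) {
    stop("lifted hit outside gene span for '", gene$gene_id, "'")
  }
  hits
}
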