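---
title: "Mapping MS/MS peptides onto genome annotation with pgmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping MS/MS peptides onto genome annotation with pgmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgmap)
```

## The problem

Shotgun proteomics identifies peptides from tandem mass spectra by
searching them against sequence databases. When those databases include
not only the annotated proteome but also cDNA, transcript (intron
containing) and raw genome translations, the identified peptides become
translation-level evidence about the genome annotation itself: a peptide
that maps inside an annotated intron, or across an exon/intron boundary,
indicates that the gene model needs revision; a peptide that maps where
no gene is annotated suggests an unannotated gene.

`pgmap` implements the analysis layer of such a proteogenomics study. It
takes a GFF3 annotation, genome and protein FASTA files, and a peptide
identification table, and produces: chromosome coordinates for every
peptide, a genomic-novelty classification per peptide, an updated GFF3
annotation carrying `peptide` evidence features, paired gene/peptide CSV
reports, a relational export, and gene-model figures.

## The method

### Locating peptides: exact six-frame search

Search engines report peptide sequences, not genome coordinates. To
recover coordinates, each peptide is searched against the six conceptual
reading frames (three forward, three on the reverse complement) of a
nucleotide target — the *unspliced* genomic span of a gene for peptides
identified from protein/cDNA/transcript databases (source tags P, C, T),
or whole chromosomes for genome-database identifications (source G).

Because an MS/MS-identified peptide must match its source translation
exactly, the search is an exact substring scan over the frame
translations rather than a heuristic alignment; it is deterministic and
exhaustive (every occurrence in every frame is reported). A hit at
amino-acid offset $a$ in forward frame $F_{f+1}$ of a target occupies
nucleotides $[f + 3a + 1,\; f + 3a + 3L]$ (peptide length $L$); reverse
frames mirror through the target length. Matches never span a stop codon
(`*` is not in the peptide alphabet), and isobaric I/L are treated as
interchangeable by default (`il_equivalent = TRUE`) since MS/MS cannot
distinguish them. Hits on gene targets are lifted to chromosome
coordinates by offset arithmetic, with hit strand determined jointly by
the frame (forward/reverse) and the gene strand.

Minimum searched peptide length defaults to 6 residues for per-gene
searches and 7 for genome-wide searches; the genome-wide search space is
roughly two orders of magnitude larger here, and short peptides produce
spurious matches at a rate that grows as $4^{-3L}$ per base scanned.

### Gene assignment

Chromosome-located hits are assigned to genes by closed-interval
intersection: a peptide belongs to every gene whose span shares at least
one base with the hit (containment and partial overlap both qualify).
Assignment is strand-agnostic; hit strand and gene strand are both
recorded in the peptide report. A hit overlapping no gene is
*intergenic*. Peptides overlapping several genes are assigned to all of
them (one GFF3 line per parent) and flagged `multi_gene`; discarding
evidence is worse than duplicating it.

### Classifying genomic context

For classification, the gene's known regions are the union of exon
intervals across all its transcripts — a peptide exonic in any isoform is
"known", which keeps novelty calls conservative under isoform choice.
The complement of that union within the gene span is intronic. With
$P$ the peptide interval:

* $P$ inside one exon block → **known**;
* $P$ inside one intron → **intronic**;
* otherwise $P$ crosses one or more exon/intron junctions. Crossing an
  exon→intron junction (the intron's 5' splice site, the *donor*) makes
  the peptide **exon-donor-spanning**; crossing an intron→exon junction
  (3' splice site, *acceptor*) makes it **exon-acceptor-spanning**.

Donor and acceptor are splice-site terms and only make sense in
transcription orientation, so the decision is strand-aware: on a
minus-strand gene the genomically-left edge of an intron is its 3'
splice site. When a peptide crosses several junctions (e.g. spans a
whole short intron), the label comes from the first junction in
transcription direction, and every crossed junction coordinate is
recorded (`boundaries_crossed`, `junctions`), so no information is lost
to the single-label scheme.

A peptide is **novel** iff it occurs as a substring of no protein
database entry (under the same I/L convention). Novelty and genomic
context are deliberately independent: a novel peptide wholly inside a
known exon reflects protein-database incompleteness, so it counts as a
novel peptide but *not* as a novel genomic feature. Novel features are
novel peptides in the intronic/donor/acceptor clusters; a gene with at
least one is flagged "to be revised".

Peptides identified from spliced search spaces that cross an exon–exon
junction match the protein but have no contiguous genomic window. They
are reported with cluster `known` and note `junction`, attributed to the
gene owning the matching protein entry; we do not fabricate split
coordinates, and spliced alignment across introns is out of scope.

### Outputs

Peptide evidence is appended to the annotation as GFF3 features of type
`peptide`, source `pgmap:<source tag>`, with
`ID=<parent>:<peptideID>` / `Parent=<parent>` attributes (e.g.
`LOC_Os06g01230.1:P62531`) plus `cluster=` and `novel=` tags, inserted
immediately after the parent gene's feature block; original lines pass
through byte-identically. Peptide IDs are the source letter plus a
1-based serial within that source in input order (`P3` is the third
protein-database peptide). Intergenic evidence goes to a separate GFF3
with no Parent. The genes and peptides reports form a master–detail
pair whose integrity (gene totals = grouped peptide counts) is asserted
before writing; the relational export adds gene/protein/cDNA/unspliced-
mRNA/peptide tables keyed by `gene_id` with foreign keys validated
first.

## The synthetic-data generator

The reference study's raw data is not publicly deposited, so validation
rests on a generator that emulates its structure with known ground
truth. Genes are built in transcription order as
`UTR5 – CDS exon – intron – … – CDS exon – UTR3`, with CDS drawn from
stop-free sense codons (so translated proteins contain no `*` by
construction) and minus-strand genes written as mirrored reverse
complements. Peptides are then cut from the appropriate translation
product per class: in-frame CDS windows (known), stop-free intron
windows (intronic), windows straddling a splice junction of the
retained-intron translation (donor/acceptor), stop-free intergenic
windows (intergenic), and spliced-protein substrings crossing an
exon–exon join (junction). Every truth interval is verified by
re-translation before emission, and peptides are made genome-unique by
rejection sampling so that classifier correctness can be separated from
mapping ambiguity; disabling uniqueness and planting duplicate coding
slices into foreign introns exercises the `ambiguous`/`multi_gene`
flags instead.

Default conditions (chosen once as plausible for a compact eukaryotic
gene space, and sized so the full validation suite runs in minutes on
one CPU): 3 chromosomes × 10 genes; 2–6 exons per gene; per-exon CDS
90–300 nt in whole codons; introns 60–300 nt; UTRs 30–90 nt; intergenic
gaps 200–1000 nt; both strands equally likely; peptide lengths 7–25
residues (tryptic-length range); 25 planted peptides per class plus 10
junction peptides; uniform identification scores in [20, 120].

What passing tests on these data do show: coordinate arithmetic,
frame/strand handling, classification, novelty logic, report integrity
and determinism are exact. What they do not show: behavior on real
search-engine output (score distributions, I/L and deamidation
ambiguity at scale, shared peptides among paralogs, alternative
isoforms beyond exon unions), or genome-scale performance — the search
is exact but single-threaded R; whole-proteome runs against a 370 Mbp
genome would need the per-gene batching the pipeline already uses, plus
patience.

## Numerical and degenerate-input choices

* Coordinates are GFF3-native 1-based closed intervals throughout; any
  half-open arithmetic is internal.
* GFF3 score/phase columns are carried as verbatim text so a
  parse → write round trip is byte-identical; missing values serialize
  as `.`.
* Unknown (`.`) strand is treated as `+` with a warning rather than
  aborting a batch.
* Annotation not sorted into contiguous gene blocks is re-grouped
  gene-wise (stable, first-appearance order) with a warning before
  peptide insertion.
* Genome-database peptides partially overhanging a gene are assigned to
  it (overlap rule) and classified on the clipped interval, flagged
  `clipped`.
* Codons containing N translate to X; X never matches a peptide residue.
* Figure layout packs peptides greedily onto rows (first row whose
  rightmost pixel is left of the new glyph), making layouts, SVG bytes
  and PNG pixels deterministic; cluster colors default to known = gray,
  intronic = red, donor = orange, acceptor = blue, intergenic = purple.

## Worked example

```{r example, eval = FALSE}
sim <- simulate_dataset(simulation_config(), seed = 1)
out <- tempfile("pgmap_run")
manifest <- run_pipeline(sim$features, sim$genome, sim$proteins,
                         sim$identifications, out)
str(manifest$counts)
```

On the default conditions this reports 135 peptides (35 known-class
P-source peptides and 100 novel ones), ~28 of 30 genes covered, 25
peptides each in the intronic, donor-spanning, acceptor-spanning and
intergenic clusters, and ~26 genes flagged for revision; the exact
gene counts vary slightly with the seed because peptides are planted in
randomly chosen genes. The same quantities are recomputed from scratch
by `scripts/acceptance.R`.

## Known limitations

* No mismatch- or indel-tolerant matching; peptides must equal their
  source translation (a hook for an external aligner would slot in at
  `find_peptide_matches`).
* No spliced (intron-aware) alignment; junction peptides are reported
  without coordinates.
* Intergenic peptides are counted and exported, not clustered into
  putative gene calls.
* No FDR modeling of identifications; filtering is threshold-based on
  the upstream engine's score and peptide length.
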