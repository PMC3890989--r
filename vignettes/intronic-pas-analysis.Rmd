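---
title: "Intronic polyadenylation signals: models, filters and estimators"
author: "intronPAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Intronic polyadenylation signals: models, filters and estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intronPAS)
library(GenomicRanges)
```

## The question

Polyadenylation signals (PAS; canonically the hexamer AATAAA) direct
cleavage and poly(A) addition at a transcript's 3' end. Hexamers this short
arise frequently by chance, so introns — which are under weak sequence
constraint — are expected to harbour many *cryptic* PAS. If such a signal
were used, transcription of the gene would be truncated inside the intron.
U1 snRNP recognition of the 5' splice site (telescripting) is thought to
silence these signals. This package implements the computational side of
asking how real that danger is in a compact animal genome:

1. **How common are intronic PAS?** Scan every annotated intron and sort it
   into one of three categories: signal *present*, signal *not found*, or
   sequence *too short* to scan.
2. **How often must they be read through?** Find *nested* genes — genes
   lying entirely inside an intron of a *host* gene — whose own PAS the
   host's polymerase must traverse.
3. **How often are they actually used?** Catalog genes annotated with a
   transcript isoform that *terminates within an intron* of a spliced
   isoform (alternative 3'-exon inclusion), and quantify the balance of the
   two isoforms from RNA-seq read densities across samples.

Every stage runs on plain GFF3 + FASTA + SAM inputs and on the package's
own fully ground-truthed simulator, so the pipeline is testable end to end
without any downloads.

## Data model and coordinate conventions

`GenomeAnnotation` holds genes, transcripts and per-transcript exons as
`GRanges`/`GRangesList` in the standard R/Bioconductor convention:
**1-based, closed intervals**, identical to GFF3's own convention, so file
I/O performs no coordinate arithmetic. All interval logic (containment,
betweenness) is expressed directly in this convention; lengths are
`end - start + 1` throughout. Introns are never read from the file: they
are derived per transcript as the gaps between consecutive exons
(`intronsByTranscript()`), which guarantees that exons and introns tile the
transcript interval exactly — a property the test suite asserts on random
annotations.

Because annotated isoforms share introns, a genome-wide intron set needs a
deduplication rule. `uniqueIntrons()` deduplicates by (chromosome, start,
end, strand) and sorts on the same key; a `per_transcript` mode retains
every per-isoform occurrence, since published genome-wide intron counts do
not always state which convention they use, and the two can differ
substantially.

## The PAS scanner

The published analyses in this area used PolyA_SVM, an external
support-vector scorer of 15 human cis-elements. Reproducing that tool's
scores is explicitly out of scope here; instead the scanner is a
transparent, configurable **weighted hexamer table**
(`defaultPasMotifs()`): AATAAA at weight 1.0, ATTAAA at 0.9, and ten common
single-base variants at 0.5, scanned with `scoreThreshold = 0.9` by
default, so only the two strong signals count as hits unless the user
lowers the threshold. Every exact match of a motif whose weight reaches the
threshold is reported; windows containing N never match. Raising the
threshold can only remove hits (a monotonicity the tests check against a
brute-force all-positions re-scan).

Two conventions in `categorizeIntrons()` deserve note:

* **Sense strand.** A PAS is functional on the transcribed strand, so the
  intron sequence is taken on the strand of the transcript that carries the
  intron (reverse complement for minus-strand genes). Whether the original
  SVM analyses scanned sense-strand-only is not documented; sense-strand is
  this package's stated choice, and a strand-symmetry test guarantees that
  mirroring the genome and flipping all strands leaves every category
  unchanged.
* **The 120-bp floor.** Sequences shorter than `minLength = 120` bp are
  categorized `too_short` regardless of content, mirroring the minimum
  input length of the scanning programs used in this field; the boundary is
  inclusive (a 120-bp intron is scanned, a 119-bp intron is not) and
  configurable.

The three categories always partition the intron set: `present` requires
not-short and at least one hit; `not_found` is the remainder.

## Nested genes

The containment rule is deliberately strict: gene B is nested in an intron
of gene A iff `start(B) > start(intron)` **and** `end(B) < end(intron)`.
A gene sharing either boundary coordinate with the intron is *not* nested.
Containment is evaluated on gene spans (outermost coordinates) against the
per-gene **union of introns over all of the host's isoforms** — read-through
concerns an intron of any isoform, so the union is the most sensitive
reading; it is
deduplicated so a gene contained in the same intron of several isoforms
yields one pair. Either strand may host either strand.

The production path uses an overlap query (`findOverlaps(type = "within")`
followed by the strict-inequality filter); an exhaustive all-pairs loop is
kept in the test suite as the oracle, and the two are required to agree
exactly on 100 seeded synthetic annotations.

`summarizeNested()` reports distinct host and nested gene counts, the
number of nested genes transcribed in their host's direction, and — since a
three-group strand breakdown can be read host-side or nested-side — both: hosts are grouped `all_same` / `all_opposite` / `mixed` by their
nested genes' strands, and per-pair relations are retained in the pair
table. The affected-gene fraction is (distinct hosts + distinct nested) /
all genes.

## Intron-terminated isoforms and the exclusion funnel

A candidate is an ordered isoform pair (spliced S, terminated T) of one
gene where, in transcription direction, T's 3' end lies strictly between
the donor (5' splice site) and acceptor (3' splice site) of one intron of
S, and T's last exon starts strictly upstream of that donor. "Strictly"
means a transcript whose last base is the final exonic base before the
donor — or one reaching the acceptor boundary — is not a candidate; both
boundary cases are unit-tested on both strands.

Two filters then narrow the catalog to genes that can be quantified cleanly:

* `excludeBoundaryOverlaps()` drops every candidate gene whose span
  overlaps any other gene's span (either strand by default — the strictest
  reading of a boundary overlap — with a same-strand-only option), because reads in shared regions cannot be attributed to a gene.
* `selectTwoForm()` keeps genes annotated with exactly two transcripts
  (the spliced and the terminated form). "Two forms" counts annotated
  transcripts, not distinct 3' ends.

Counts of this architecture can be stated per gene or per isoform-pair
event; `catalogIntronTerminated()` reports both (`nCandidateGenes`,
`nCandidatePairs`).

## Read-density quantification

For a candidate gene and one sample, with mean per-base coverage depth
$d(\cdot)$ over a region:

* spliced level $S = d(\text{3'-terminal exon of the spliced isoform})$;
* intron-terminated level
  $I = d(\text{donor} \to \text{termination}) -
       d(\text{termination} \to \text{acceptor})$,
  the subtrahend being signal attributable to unspliced pre-mRNA, which
  covers both segments equally;
* proportion $\theta = I / (I + S)$.

Depth counts each CIGAR-aligned base once: M/=/X consume depth, N (spliced
junctions) and D add none — so junction reads of the spliced isoform
contribute nothing inside the intron, which is exactly the separation the
difference formula needs. Numerical choices: a negative difference
(possible under noise) is clamped to zero so $\theta \in [0,1]$, with the
raw value reported alongside; when $I + S = 0$ the proportion is `NA`
(undefined), never 0/0. Multi-mapped reads count once per alignment record.
Whether a reported read density counts reads or read-bases per position
is often ambiguous; per-base depth is the default and a read-count mode is
exposed (`regionMeanDepth(mode = "read")`). No cross-sample normalization
is applied: the levels are raw read-density units by design, as isoform
*ratios* within a gene and sample are scale-free (the tests verify that
duplicating every read leaves $\theta$ unchanged).

## Expression groups and the heat map

Across samples, `classifyGenes()` assigns each gene exactly one label:
`no_intronic_form` ($I$ at or below the noise floor everywhere),
`no_splicing` ($S$ at or below the floor everywhere), `switching` (both
isoforms above the floor somewhere and the $\theta$ range across samples at
least `switchDelta`), else `unclassified`; `misannotated` is applied only
from a user blacklist, since judging an annotation erroneous is a manual
call. The thresholds — `noiseFloor = 1.0` read-density unit and
`switchDelta = 0.2` — are this package's own operational defaults: a
qualitative notion of baseline noise pins down neither, so the values are documented, attached to the output as
attributes, and configurable rather than presented as inferred.

`buildHeatmapMatrix()` emits three rows per gene — spliced level,
intron-terminated level, proportion — against samples;
`plotIsoformHeatmap()` renders it (no clustering, a gap per gene). Levels
and proportions live on different scales; the plot shows levels relative to
the matrix-wide maximum with a row annotation distinguishing the two, a
deliberate simplification of a two-colour-scale figure.

## The simulator: what it emulates, and what it does not

`simConfig()` defaults encode the architecture statistics the analysis
targets: 55% of introns below the 120-bp floor; two thirds of long introns
carrying a PAS; ~6% of genes hosting one nested gene with 44% of nested
genes on the host strand; ~3% of genes carrying an intron-terminated
isoform pair, of which 42% get an overlapping neighbour (boundary-overlap
exclusion cases) and 70% of the remainder a third isoform (two-form
exclusion cases). Counts are allocated by deterministic rounding — the
planted truth is exact, not a sampled expectation — and all randomness
(lengths, placement order, strands, PAS positions, read starts) derives
from one seed, giving byte-identical outputs.

The genome sequence is random A/C/G/T that is *scrubbed* of every scoring
hexamer (and reverse complements) by point substitution before AATAAA is
planted at recorded positions, so the planted-PAS fraction is recovered
exactly by construction, not approximately. Reads are drawn with uniform
start positions along each expressed isoform at the configured depth
(default 50x, read length 50 bp); for candidate genes a per-gene,
per-sample $\theta$ splits the depth between the terminated and spliced
isoform, emulating developmental switching profiles (0 / 1 / alternating
0.15–0.85 for the three planted groups). Spliced reads receive N-gapped
CIGARs; terminated-isoform reads never pass the termination point; optional
ungapped pre-mRNA background reads can be added (`unsplicedDepth`), whose
contribution the difference estimator cancels by construction.

Deliberately **not** modelled: sequencing errors, fragment-length and
positional biases, expression-level distributions across genes, multi-chromosome
genomes, and ambiguous multi-mapping. Passing tests therefore demonstrate
the correctness of the interval logic and the estimator under its own
assumptions — uniform coverage with edge effects — not robustness to the
full noise structure of real libraries. On real data the known main risks
are coverage non-uniformity within the intron (which biases the density
difference) and annotation errors (which the `misannotated` blacklist
leaves to the analyst).

## Validation scale

The checks the package runs in its test suite and acceptance script use
problem sizes chosen to exercise every code path while keeping a full run
in minutes on one core: oracle-equivalence of the structural stages on 100
seeded annotations of 40–140 genes; $\theta$ recovery on the grid
{0, 0.25, 0.5, 0.75, 1} at 50x depth with two replicate genes per value
(mean absolute error required below 0.05); depth conservation of
`regionMeanDepth()` against a naive per-base pileup on gapped and ungapped
read sets; and exact recovery of all planted architecture counts on a
400-gene annotation emulating genome-scale rates. Reproducing
genome-release-specific counts is possible in principle by pointing
`readGenomeAnnotation()` at the corresponding GFF3 release, but requires
those files and an external scorer, and exact agreement is not expected
across annotation-parsing conventions; it is not part of the automated
checks.

## Limitations

* The hexamer scanner is a stand-in for SVM-based PAS prediction: it has
  no positional model and no E-values, and its `present` fraction on real
  genomes will differ from SVM-derived figures.
* Mutually overlapping genes without containment are not resolved into
  host/nested roles.
* Quantification trusts the annotated termination point; it does not
  re-estimate 3' ends from read pileups.
* No statistical test accompanies the `switching` call; it is a
  descriptive threshold rule.
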