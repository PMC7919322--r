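---
title: "Filtering splice junctions for two-pass alignment of long RNA reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filtering splice junctions for two-pass alignment of long RNA reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spliceguide)
```

## The problem

Nanopore direct RNA sequencing (DRS) reads full-length mRNA molecules 3'
to 5' with a per-base error rate high enough that spliced aligners
routinely misplace introns. Basecall errors near exon boundaries shift the
apparent splice junction by a few nucleotides, and short internal exons
sometimes fail to align at all, collapsing two real introns into one
spurious one. Because alignment errors of this kind recur at the same loci
across reads, they masquerade as well-supported novel junctions.

Two-pass alignment addresses this: align once, harvest the observed splice
junctions, *filter* them, and realign with the surviving junctions
supplied to the aligner as scoring bonuses. spliceguide implements the
filtering, the metrics it relies on, an annotation-aided variant, a DRS
read simulator for building ground-truth benchmarks, and the evaluation
machinery. The second alignment pass itself stays with the spliced
aligner (guide-junction BED in, junction bonus 12, species-appropriate
maximum intron length: 10,000 nt for Arabidopsis, 200,000 nt for
human/mouse, 5,000 nt for yeast).

## Junction metrics

All metrics are computed from long-form cs difference strings, which
encode matches, mismatches, indels and intron skips per alignment. Only
primary alignments contribute.

**Junction alignment distance (JAD).** Per read, the length of the
shorter of the two exact-match operations immediately flanking the intron;
zero when a mismatch or indel (or the alignment boundary) abuts the
intron. Per junction, the maximum over its reads. A junction crossed by
even one read that aligns cleanly for several nucleotides on both sides is
very likely genuine; the shipped threshold is a JAD of 4 nt.

**Read count.** The number of supporting primary alignments. Count and
JAD correlate strongly, so count mainly serves as a tie-breaker currency
for the primary-site metric.

**Intron motif.** The first two plus last two intron bases, read from the
reference. GT..AG, GC..AG and AT..AG are canonical (for budding yeast,
configure `canonical_motifs = "GTAG"` only). A locus whose forward-strand
motif is the reverse complement of a canonical motif is reported in
canonical orientation with strand `-`; anything else is unstranded (`.`).
Junctions are keyed by `(chrom, start, end)` only — strand is a derived
property, and conflicting read-level inferences produce a warning rather
than two records.

**Primary donor/acceptor.** A donor site is *primary* when no alternative
donor within 20 nt (inclusive) has higher pooled read support; read-count
ties are broken by site JAD, and a tie on both leaves neither site
primary. Acceptors are treated symmetrically. Sites pool their counts
across junctions sharing the position; `+` and `.` strands compete
together and `-` separately, so a strand-inference failure cannot
manufacture spurious competition. Spurious junctions born of local
misalignment sit a few nucleotides from a stronger genuine site and fail
this test.

## The two rule trees

Both shipped classifiers are explicit five-node decision trees
(`shipped_tree1()`, `shipped_tree2()`); the node tables can be inspected,
counted and replaced wholesale, and `tree_rule_expression()` flattens them
to the equivalent boolean rule.

Tree 1 uses alignment metrics only:

```{r}
cat(tree_rule_expression(shipped_tree1()))
```

i.e. keep a junction iff its motif is canonical and it either reaches the
JAD threshold or is primary at both ends.

Tree 2 replaces the canonical-motif test with splice-site sequence scores
(next section), combined across the donor and acceptor site by their
minimum — a junction is only as trustworthy as its weaker site:

```{r}
cat(tree_rule_expression(shipped_tree2()))
```

Junctions passing the JAD threshold are kept unless the score drops below
a low-confidence threshold of 0.1 (false-positive removal); junctions
failing it are rescued when primary at both ends with a score of at least
0.6. The exact node arrangement of the original figures is not recoverable
from text, so the shipped trees realize the published textual rule; a user
transcribing the figures can substitute their own node table via the
`tree` argument. The published tree-training hyperparameters are recorded
for reference, but the shipped trees are fixed rules — retraining them is
out of scope.

## Splice-site sequence models

Genuine splice sites carry sequence signal beyond the terminal
dinucleotides (the extended donor consensus and the polypyrimidine tract
before the acceptor). spliceguide extracts a 128 nt genomic window centred
on each *unique* donor and acceptor site (reverse-complemented for
minus-strand sites, N-padded at contig edges), one-hot encodes it into
4 × 128 = 512 binary features, and fits L2-regularized logistic
regression — independently for donors and acceptors. Labels come from
tree 1: a site is positive when it participates in at least one junction
tree 1 kept.

Scoring is strictly out-of-bag: sites are split into 6 seeded, stratified
folds; each fold is scored only by the model trained on the other five
(83.3% of the data), so scores can feed tree 2 without leakage. Ridge
regularization (`lambda = 0.01`) is used because the features are binary
and near-collinear one-hot blocks; no feature scaling is applied, as
none is needed for 0/1 inputs. `N` positions encode as all-zero blocks,
which keeps the feature count fixed and is neutral under a linear model.
Degenerate inputs degrade loudly rather than fail: single-class labels, or
a class too small to stratify across folds, yield flat scores of 0.5 with
a prominent warning.

## Annotation-aided cascade

When a (possibly incomplete) annotation exists, its junction set provides
noisy labels: annotated junctions are genuine; unannotated observed
junctions are *mostly* spurious. The cascade refines this in three
stages: (1) an ensemble of 100 fully randomized trees (extra-trees splits,
random thresholds) on the junction metrics — count, max JAD, canonical
flag, primary flags, plus a one-hot of the four motif characters
(`motif_features = TRUE`) — scored out-of-bag by the same seeded k-fold
scheme as the sequence models; (2) refined labels (`stage1_prob >= 0.5`)
train the sequence models; (3) a final randomized forest on metrics plus
both sequence scores, again out-of-bag, yields `final_prob` and the
verdict at 0.5. K-fold out-of-bag (rather than bootstrap out-of-bag) keeps
all three stages deterministic under the seed and uniform with the LR
procedure; the 0.5 refinement threshold is the natural midpoint. With
`retain_annotated = TRUE`, observed annotated junctions are kept even when
the model rejects them, so annotation false negatives cost nothing.

When the annotation is nearly complete, almost every unannotated observed
junction really is spurious and the cascade behaves like a sharp filter;
as missingness grows, genuine-but-unannotated junctions resemble the
annotated positives in metric space and are recovered. At extreme
missingness the labels stop being informative and the annotation-free mode
is preferable.

## The read simulator

To benchmark against a known truth, reads are simulated from a
transcriptome with error profiles learned from real (or synthetic)
splicing-free transcriptome alignments:

1. **Model building.** Pairwise alignments are reconstructed from cs tags
   (one column per reference base; insertions attach to the preceding
   reference base's emitted fragment; refskips are ignored) and inverted
   to the 3' to 5' sequencing direction. Basecalls across reference
   homopolymers of ≥ 5 nt are collected into a homopolymer call table and
   the reference run is replaced by its basecall, so homopolymer errors
   are not modelled twice. The altered alignments then feed a Markov
   model: the distribution of (emitted fragment, alignment state) given
   the current + previous four reference bases and previous four states.
2. **Simulation.** Each transcript is reversed and primed with 10 nt of
   oligo(A), so the chain starts from the all-A, all-match context.
   Reference homopolymers draw whole-run emissions from the homopolymer
   table; other positions draw from the transition table. Unseen contexts
   back off — drop the oldest state, then the oldest base, then copy the
   base error-free — with counters reported. The emission is reverted to
   5' to 3' and 10 nt are trimmed from the 5' end, mimicking signal loss
   at the end of sequencing. The 3' coverage bias of DRS is deliberately
   not modelled: reads are full length.

Under a zero-error model the round trip is exact: the read equals its
transcript minus the 10 nt 5' trim plus the 10 nt oligo(A) tail. Base
qualities in FASTQ output are a constant placeholder; nothing downstream
uses them.

## Evaluation

Alignments of simulated reads are judged by intron chain — the ordered
introns of the alignment, ignoring start/end positions. A read is
*correct* when its chain equals its source transcript's chain exactly;
*misassigned* when it equals a different reference transcript's chain;
*novel spurious* when its chain is absent from the reference or when a
spliced read aligns intronless. Intronless reads from intronless
transcripts are flagged `unspliced_correct` and excluded from percentage
summaries. Transcript quantification counts reads whose chain matched each
reference transcript, compared to the known simulation counts by
Spearman's rank correlation (average ranks). Annotation missingness
experiments drop transcript isoforms (not genes) independently at a given
rate, seeded.

## The synthetic fixture

`fixture_spec()` / `make_fixture()` generate the self-contained test
world: a single-chromosome genome of multi-exon genes (alternating
strands), exon-skipping isoforms, canonical intron motifs (94% GT..AG, 4%
GC..AG, 2% AT..AG), and cs-tagged alignments realizing three regimes —
clean junctions with high JAD, genuine junctions degraded to JAD 0 by an
adjacent mismatch (15% of read-junctions), and spurious junctions shifted
by 1–10 nt carried by 20% of junction crossings. Reflecting how aligners
misplace junctions in real data, 67% of spurious variants are planted with
canonical dinucleotides at the shifted termini, and 10% align cleanly
(high JAD); the rest have their JAD capped at 0–3. Genuine sites carry an
extended donor (`GTAAGT`) and acceptor (`TTTTTCAG`) consensus so sequence
models have learnable signal. Per-base mismatch noise is 2% and coverage
is 4–10 reads per isoform.

The fixture writes a real indexed BAM so the extraction code is tested
through its production path. What it does *not* emulate — indel errors in
alignments, realistic expression skew, branchpoint structure, 3' coverage
bias, genuinely novel (unannotated, unshifted) junctions — bounds what
passing tests show: they demonstrate that the implementation reproduces
the method's behaviour under the method's own assumptions, not performance
on any particular real dataset.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; GTF/GFF3 is
  converted on read, BED passes through.
* Records missing cs tags are skipped with a warning (no CIGAR/MD
  fallback — the method is defined on cs strings); secondary and
  supplementary alignments are skipped with a counter.
* A refskip shorter than 4 nt is a parse error (no room for both
  dinucleotides); malformed cs tokens report their character offset.
* Empty prediction sets define precision as 1 against an empty truth set
  and 0 otherwise, logged either way.
* All stochastic steps (fold shuffling, forest growth, simulation) are
  functions of a single integer seed; reruns are byte-identical.

## Problem sizes

The test-suite and the bundled acceptance script run everything on
generated data: a 140-gene fixture (~700 genuine junctions plus a
comparable shifted-spurious population, ~2,300 reads) for the filtering
and cascade benchmarks, 1,000 random instances of up to 50 junctions for
the primary-site oracle comparison, and ~120,000 simulated bases for the
error-rate recovery check. These sizes give stable statistics for the
thresholds being checked while keeping a full run in the minutes range on
one CPU.

## Known limitations

* The shipped rule trees reproduce the published textual decision rules;
  users wanting the exact figure-borne node arrangement can supply their
  own node table.
* Sequence models are linear; they capture positional consensus but not
  higher-order interactions or branchpoint positional variation.
* The simulator models substitution/indel context and homopolymer calls,
  not signal-level effects or poly(A) length.
* Junction merging across replicates (`merge`) sums counts and keeps the
  first strand seen; the original multi-replicate pooling semantics are
  not specified in the method description.
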