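# spliceguide

Filtered two-pass spliced alignment guidance for long, high-error RNA
reads.

Spliced aligners routinely misplace introns in nanopore direct RNA
sequencing (DRS) alignments: basecall errors near exon boundaries shift
the apparent splice junction by a few nucleotides, and short exons
collapse into single spurious introns. Because these errors recur across
reads at the same loci, naively feeding first-pass junctions back to the
aligner amplifies them. spliceguide extracts every junction observed in a
first-pass BAM together with alignment-quality metrics, classifies
junctions as genuine or spurious, and writes the survivors as a 6-column
BED that spliced aligners accept as a guide-junction set for a second
pass. It is aimed at people building transcriptome annotations or
quantifying isoforms from long-read RNA data, with or without a reference
annotation.

## Method

For every junction *j* observed in primary alignments, spliceguide
computes:

* **JAD(j)** — junction alignment distance: per read, the length of the
  shorter exact-match block flanking the intron (0 if a mismatch/indel
  abuts it); per junction, the maximum over reads.
* **count(j)** — supporting primary alignments.
* **motif(j)** — terminal intron dinucleotides; canonical = GT..AG,
  GC..AG, AT..AG (configurable; yeast: GT..AG only).
* **primary donor/acceptor(j)** — no alternative site within 20 nt has
  higher pooled read support (count ties broken by JAD; double ties leave
  neither primary).

Two five-node rule trees produce verdicts. Tree 1 (metrics only):

    keep  ⇔  canonical ∧ ( JAD ≥ 4  ∨  (primary donor ∧ primary acceptor) )

Tree 2 replaces the motif test with splice-site sequence scores
*s* = min(donor score, acceptor score), from L2-regularized logistic
regression on one-hot encoded 128-nt genomic windows centred on each
unique site (512 features), trained on tree-1 labels with 6-fold
cross-validation and scored strictly out-of-bag:

    keep  ⇔  ( JAD ≥ 4 ∧ s ≥ 0.1 )  ∨  ( JAD < 4 ∧ primary both ∧ s ≥ 0.6 )

An annotation-aided mode replaces the fixed trees with a cascade of
randomized forests bootstrapped from annotation-derived labels
(annotated = genuine), refines the labels out-of-bag, retrains the
sequence models, and optionally retains all observed annotated junctions.
The package also ships the DRS read simulator used for benchmarking
(homopolymer call table + 4th-order Markov basecall model, oligo(A)
priming, 5' trim), intron-chain based evaluation of alignments, and a
deterministic synthetic fixture generator. See the vignette
(`vignettes/two-pass-junction-filtering.Rmd`) for the full method
description.

## Worked example

Generate a small synthetic world (12 genes, exon-skipping isoforms,
shifted spurious junctions, 2% mismatch noise) and run the full
annotation-free workflow:

```r
library(spliceguide)
spec <- fixture_spec(n_genes = 12L, seed = 7L)
fix  <- make_fixture(spec, "demo")          # genome.fa, annotation.gtf, reads.bam, truth
res  <- score_junctions(fix$paths$bam, fix$paths$genome, filter_config(seed = 7L))
head(res$records, 5)
```

```
          key strand motif count max_jad is_canonical is_primary_donor donor_score acceptor_score verdict_tree1 verdict_tree2
 chr1:339-426      +  GTAG     1       1         TRUE            FALSE   0.8625016      0.0282414         FALSE         FALSE
 chr1:345-432      +  GTAG     5      61         TRUE             TRUE   0.2113013      0.9011725          TRUE          TRUE
 chr1:345-635      +  GTAG     4      78         TRUE             TRUE   0.2113013      0.8404750          TRUE          TRUE
 chr1:350-640      +  GTAG     1       1         TRUE            FALSE   0.8953215      0.6011080         FALSE         FALSE
 chr1:540-629      +  GTAG     3       3         TRUE            FALSE   0.2066636      0.8511106         FALSE         FALSE
```

The first row is a spurious junction shifted 6 nt from the genuine
`chr1:345-432`: one read, JAD 1, outcompeted for primary status — both
trees discard it. The genuine junction beneath it has 5 reads, JAD 61 and
primary status at both ends, and is kept. Junction-level performance
against the generator's truth set:

```r
truth <- fix$junctions$key
junction_prf(res$records$key[res$records$verdict_tree1], truth)
#> precision 0.923  recall 1.000  f1 0.960
junction_prf(res$records$key[res$records$verdict_tree2], truth)
#> precision 0.952  recall 1.000  f1 0.976
```

The sequence-model stage removes tree-1 false positives (shifted
junctions that landed on planted canonical dinucleotides with clean
flanks), raising precision. Writing the guide set for the second
alignment pass:

```r
keep <- res$records$verdict_tree2
write_junction_bed(res$records[keep, ], "guide_junctions.bed")
```

The same workflow is available from a shell via the bundled script:

```sh
exec/spliceguide score --bam demo/reads.bam --genome demo/genome.fa \
    --out-prefix demo/scored --seed 7
exec/spliceguide score-aa --bam demo/reads.bam --genome demo/genome.fa \
    --annotation demo/annotation.gtf --retain-annotated --out-prefix demo/aa
```

Subcommands: `score`, `score-aa`, `merge`, `build-error-model`,
`simulate`, `evaluate`, `make-fixture`. Every run writes a JSON manifest
(config snapshot, input digests, seed, version).

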