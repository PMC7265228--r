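# ighdarch

Comparative analysis of duplicated immunoglobulin heavy-chain diversity
(DH) gene clusters, built around the question of how an *ultralong* DH
gene can arise: cattle encode CDR H3 loops of up to ~70 amino acids, and
almost all of that length comes from a single germline DH segment
(IGHD8-2, 49 codons) sitting in one of three near-identical D-gene
clusters. `ighdarch` provides the pieces needed to reconstruct — and to
stress-test on simulated ground truth — the genomic account of such a
gene: recombination-signal-sequence (RSS) detection, RSS-guided gene
calling and cluster segmentation, pairwise alignment with one fixed
percent-identity definition, paralog mapping with deletion /
transposition / missing-family calls, tandem-repeat decomposition, and
donor-pair scoring for DH–DH fusion origins.

It is aimed at immunogenetics and comparative-genomics researchers who
work with germline antibody loci (IMGT-style annotations, FASTA/GenBank
records, BED/GFF3 tracks) and want every printed identity or event call
to be reproducible from a seed and a parameter set.

## The model in brief

* A **D gene** is a coding segment flanked by two RSSs with 12-bp
  spacers. On the top strand the 5' RSS reads nonamer–spacer–heptamer
  (heptamer adjacent to coding) and the 3' RSS reads
  heptamer–spacer–nonamer. A scan reports every 28-nt footprint whose
  heptamer and nonamer are within configurable Hamming distances of a
  consensus.
* **Percent identity** of an alignment is `100 · matches / columns`,
  where a column matches iff both characters are equal and neither is a
  gap or `N`; gap columns stay in the denominator. Alignments are
  affine-gap (Gotoh), scores `+5 / −4`, gap open `−16`, extend `−4`
  (EMBOSS-Matcher DNA defaults), a gap of length *k* costing
  `open + (k−1)·extend`.
* A **fusion hypothesis** (d5, d3 → target) is scored as

  ```
  composite = 0.35·prefix/100 + 0.35·suffix/100
            + 0.15·(1 − rss5/28) + 0.15·(1 − rss3/28)
  ```

  where `prefix`/`suffix` are terminal identities of each donor coding
  against the target (local alignments anchored at the target terminus,
  X-drop-limited) and `rss5`/`rss3` are total RSS Hamming distances.
* The **simulator** replays the hypothesized history as executable
  events — cluster duplication, point substitution, segmental deletion
  fusing two genes while keeping the outer RSSs, gene transposition,
  repeat expansion — and logs every edit so that replaying the truth log
  reproduces the emitted locus byte-for-byte.

## Worked example

Simulate a three-cluster locus whose first cluster carries a scripted
deletion-fusion, a transposition and a repeat expansion, then recover
all three events:

```r
library(ighdarch)

sim      <- simulate_locus(sim_params(seed = 42))
genes    <- call_genes(sim$seq, max_heptamer_mm = 0, max_nonamer_mm = 0)
clusters <- segment_clusters(sim$seq, genes)
clusters[[1]]
#> <dh_cluster> 1: 5 genes, span [2500,5261) (2761 nt)
# clusters 2 and 3 keep 6 genes over 3576 nt: cluster 1 lost one gene
# and ~800 nt, like the published 3480 vs 3838/3844 nt contrast

map_paralogs(clusters[[1]], clusters[[2]])$order_events[, 1:3]
#>             type gene_a gene_b
#> 1 missing_family   <NA>     D8
#> 2  transposition     D4     D6
#> 3   length_delta     D2     D9

compare_intergenic(clusters[[1]], clusters[[2]])[, c(2, 3, 5, 6)]
#>    between length coverage deleted_in_a
#> 3   D8..D9    674        0         TRUE    # the fused-away interval
#> (other rows: coverage 1, not deleted)
```

The gene that replaced the fused pair ranks its true donors first:

```r
fused <- clusters[[1]]$genes[[2]]            # the novel long gene
rk <- score_fusion(fused, clusters[[2]]$genes)
head(rk$table[, c(1, 2, 3, 5, 7, 8, 12)], 3)
#>   donor5 donor3 prefix_identity suffix_identity rss5_diffs rss3_diffs composite
#> 1     D8     D9           96.36           98.04          0          0    0.9804
#> 2     D8     D7           96.36           78.57          0         10    0.8587
#> 3     D9     D7           57.14           78.57         10         10    0.6679
```

`D8`/`D9` are exactly the genes the truth log fused (reference ordinals
3 and 4): a ~96% 5'-prefix identity, ~98% 3'-suffix identity and
identical flanking RSSs — the same evidence pattern that identifies an
IGHD6-family 5' donor and IGHD7-family 3' donor for the real ultralong
gene. The packaged RSS table reproduces that real-data signal without
any download:

```r
s <- ighd_rss_sites()
compare_rss(s[["IGHD8-2"]]$rss3, s[["IGHD7-3"]]$rss3)$total_diffs  # 0
compare_rss(s[["IGHD8-2"]]$rss5, s[["IGHD6-2"]]$rss5)$total_diffs  # 0
```

## Command line

```sh
Rscript -e 'ighdarch::ighd_cli()' simulate --seed 7 --out-dir out/sim
Rscript -e 'ighdarch::ighd_cli()' annotate --input out/sim/locus.fasta \
    --out-dir out/ann --max-heptamer-mm 0 --max-nonamer-mm 0
```

Subcommands: `annotate`, `compare`, `fusion`, `repeats`, `simulate`,
`report`. Exit codes: 0 success, 2 usage/config error, 3 input format
error. Configuration is a JSON file (`--config`) with per-flag
overrides.

## Vignette

`vignettes/ighd-architecture.Rmd` documents the model, every tunable
parameter with its default and rationale, what the simulator does and
does not emulate, and the package's numerical choices.
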