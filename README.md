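# mitocharter

Characterization toolkit for multichromosomal plant mitochondrial genomes.

Plant mitochondrial genomes often assemble not as one circle but as many
circular "subgenomes" — in orchids, around twenty chromosomes of 20–50 kb.
Characterizing such a genome means running a standard battery of analyses,
and `mitocharter` implements that battery as tested R functions:

* **Simulation with ground truth** — multichromosomal genomes with planted
  genes, microsatellites, tandem arrays, dispersed repeats, plastid-shared
  and NUMT-like nuclear segments, C-to-U editing events, and simulated long
  reads, all recorded in a truth manifest (`sim_config()`,
  `generate_mitogenome()`, `generate_companion_genomes()`,
  `simulate_reads()`, `apply_editing_truth()`).
* **Read recruitment** — iterative seed-extension baiting of mitochondrial
  long reads from a mixed pool: candidates match a core gene by > 50 bp,
  seeds are the best-ranked candidates, and any read overlapping a recruited
  read by ≥ 1 kb at ≥ 70% identity is added until a fixpoint
  (`select_candidates()`, `choose_seed()`, `recruit_iteratively()`).
* **Codon usage** — codon counts with separate stop tallies, positional GC,
  RSCU (`RSCU_j = n · c_j / Σ c` within each synonymous family), Wright's
  effective number of codons `Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆`, and
  copy-weighted start/stop tallies that resolve edited stops like
  `CGA(TGA)` (`count_codons()`, `rscu()`, `effective_number_of_codons()`,
  `start_stop_summary()`).
* **RNA editing** — classification of C→U codon transitions by amino-acid
  hydrophobicity effect (hydrophobic = {A, I, L, F, M, P, V, W}) and a
  reference-protein comparative predictor proposing minimal C→T edits at
  codon positions 1–2 (`classify_edit()`, `summarize_edits()`,
  `predict_edit_sites()`).
* **Repeats** — microsatellites with MISA semantics (minima
  1-10 2-5 3-4 4-3 5-3 6-3) and complementary-rotation canonical classes;
  tandem arrays with > 6 bp units under the TRF +2/−7 weights; dispersed
  forward/palindromic repeats by word-size-7 seeded self-comparison
  (`find_ssrs()`, `canonical_motif()`, `find_tandem_repeats()`,
  `find_dispersed_repeats()`, `repeat_summary()`).
* **DNA transfer** — homologous fragments between genome pairs at the MTPT
  screening thresholds (identity ≥ 70%, length ≥ 30 bp, E ≤ 1e-5),
  overlap-merged coverage, gene containment, and ≥ 300 bp synteny blocks
  (`find_homologous_fragments()`, `merged_coverage()`,
  `genes_fully_contained()`, `synteny_blocks()`).
* **Molecular evolution** — Nei–Gojobori (1986) Ka/Ks with pathway-averaged
  difference counting and Jukes–Cantor correction, and Nei's nucleotide
  diversity π (`ng86_kaks()`, `pairwise_kaks_table()`,
  `nucleotide_diversity()`).

The bundled reported tables for the *Cymbidium ensifolium* multichromosomal
mitogenome (protein-coding genes with start/stop codons and copy numbers, the
530-site editing transition multiset, and the microsatellite class counts)
ship as plain-text inputs under `inst/extdata/` and drive the desk-scale
checks (`reported_pcg_genes()`, `reported_editing_sites()`,
`reported_ssr_classes()`).

## Worked example

Classify the reported editing transitions and summarize them:

```r
library(mitocharter)
ev <- classify_edit_table(reported_editing_sites())
s  <- summarize_edits(ev)
round(s$class_percent, 2)
#> hydrophilic-hydrophilic hydrophilic-hydrophobic        hydrophilic-stop
#>                   13.21                   48.68                    0.38
#> hydrophobic-hydrophilic hydrophobic-hydrophobic
#>                    9.25                   28.49
```

Over the 530 sites, 41.70% leave hydrophobicity unchanged and 2 events create
a stop codon (`CGA → TGA`).

Simulate a small multichromosomal genome and run detectors against it:

```r
cfg <- sim_config(n_chromosomes = 3, chrom_length_range = c(20000, 25000),
                  rng_seed = 7)
sim <- generate_mitogenome(cfg)
genome_stats(sim$genome)$per_chromosome
#>   chromosome length        gc
#> 1       chr1  21490 0.4455561
#> 2       chr2  24571 0.4447112
#> 3       chr3  22753 0.4460071

head(find_ssrs(sim$genome$seq[["chr1"]], chrom = "chr1", circular = TRUE), 3)
#>   chromosome start  end motif canonical_class unit_length copy_number
#> 1       chr1  2391 2403  AAAC       AAAC/GTTT           4           3
#> 2       chr1  4258 4270  ATAG       AGAT/ATCT           4           3
#> 3       chr1  7137 7152 GAGAG     AGAGG/CCTCT           5           3

comp <- generate_companion_genomes(sim, cfg)
fr   <- find_homologous_fragments(sim$genome, comp$plastome)
cov  <- merged_coverage(fr, sim$genome)
sprintf("%d fragments, %d bp covered (%.2f%%)", nrow(fr), cov$covered_bp,
        100 * cov$fraction)
#> [1] "13 fragments, 19906 bp covered (28.93%)"
```

The coverage fraction is high here because the default plastid-shared
spectrum (37 bp – 11 kb) is planted into a deliberately small 3-chromosome
genome; on a 10-chromosome ~300 kb fixture it lands near 7%.

Ka/Ks on a two-codon-difference pair:

```r
ng86_kaks(c(a = "ATGTTTAAAGAAGGG", b = "ATGCTTAGAGAAGGC"))[, c("ka", "ks", "ratio")]
#>         ka       ks    ratio
#> 1 0.179963 0.571605 0.314838
```

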