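---
title: "Methods: simulating and characterizing multichromosomal plant mitogenomes"
author: "mitocharter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and characterizing multichromosomal plant mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocharter)
```

# Scope

Plant mitochondrial genomes are frequently assembled not as one circle but as
a set of circular "subgenomes" — in orchids, around twenty chromosomes of a
few tens of kilobases each. Characterizing such a genome involves a standard
battery of analyses: recruiting the mitochondrial long reads out of a mixed
sequencing pool, codon-usage statistics over the protein-coding genes,
prediction and classification of C-to-U RNA editing sites, detection of
microsatellites, tandem arrays and dispersed repeats, detection of
plastid-derived and nucleus-shared homologous fragments, and per-gene
molecular-evolution statistics (Ka/Ks and nucleotide diversity).

`mitocharter` implements this battery as testable functions. Because the real
inputs are large downloads, the package includes a first-class simulator that
builds multichromosomal genomes with *planted, truth-tracked* features, so
every detector can be scored against known ground truth at desk scale. This
vignette records the models, the parameters that matter, and the numerical
decisions.

# The synthetic genome generator

`sim_config()` + `generate_mitogenome()` build `n_chromosomes` circular
chromosomes with i.i.d. background bases at `gc_target`. The defaults are the
study conditions for a multichromosomal orchid mitogenome: 19 chromosomes of
21,995–48,212 bp at 44% GC, one to a few protein-coding genes per chromosome,
and ~10 kb long reads at 5% substitution error and 20-fold depth.

Design choices:

* **Background model.** Bases are i.i.d. at the target GC; no higher-order
  Markov structure. The downstream detectors consume composition and planted
  features, not realism — chance k-mer sharing is what the null distributions
  need, and i.i.d. background gives analytic control over it.
* **Coordinates.** All manifests are 0-based half-open on the forward strand.
  GFF3 emission converts to 1-based inclusive; a feature crossing the origin
  of a circular chromosome is emitted as two parts sharing one ID.
* **Planted features.** Genes (ATG start, stop from TAA/TAG/TGA, stop-free
  body), microsatellites at or above the MISA copy minima, tandem arrays with
  >6 bp units (optionally imperfect via counted substitutions), and dispersed
  repeat copies (forward or reverse-complemented) at an exact Hamming
  identity: `round((1 - identity) * length)` substitutions at distinct
  positions, so truth identity is exact rather than a sampling expectation.
* **Companion genomes.** `generate_companion_genomes()` copies mitochondrial
  segments into a circular plastome and into linear nuclear chromosomes. The
  plastid-shared spectrum spans 37 bp to 11 kb at identities 0.75–1.0,
  mirroring the observed spectrum of plastid-derived fragments in
  multichromosomal orchid mitogenomes; segments at low identity are long,
  because a short low-identity fragment is undetectable at E ≤ 1e-5 for any
  method (see the E-value section). Nuclear shared segments default to
  200–800 bp — NUMT-like, and deliberately below the 1 kb recruitment
  overlap so that read-origin labels are a valid recruitment truth set.
* **Editing truth.** `apply_editing_truth()` plants Poisson-many C→T changes
  per CDS at codon positions 1 or 2. By default only nonsynonymous,
  non-stop-creating edits are planted: transcripts stay translatable and
  predictor recall is well defined. The *classifier* still handles stop gains
  and double-base edits, which occur in real editing tables.
* **Reads.** Lengths are normal around `mean_len` (sd 10%, truncated to
  0.5–1.5×), starts uniform, circular templates yield origin-spanning reads,
  errors are uniform substitutions. Substitution-only errors keep every
  identity computation analytic; instrument-specific error profiles and
  indels are out of scope.

Determinism: the same `sim_config()` (including `rng_seed`) reproduces
byte-identical FASTA/FASTQ/GFF3/manifest output.

What passing tests on these fixtures do *not* show: performance on real
repeat-dense plant mitochondria (recombination-mediated large repeats,
nested repeat families), chimeric or indel-rich long reads, and biased base
composition. The detectors' thresholds are the field-standard ones, but
recovery rates on real data will be lower than on this clean background.

# The local-similarity engine

One compiled seed–chain–extend engine backs read recruitment, dispersed
repeats, interorganellar fragments and synteny blocks (`local_matches()`):

1. exact k-mer seeds against a hash index of the target (both strands);
2. seeds grouped by **exact diagonal** — substitutions never shift a
   diagonal, so for substitution-dominated data every true local match lives
   on one diagonal; a diagonal's run is split when consecutive seeds are more
   than `max_gap` (default 500 bp) apart;
3. X-drop ungapped extension outwards, then a maximal-scoring-segment trim
   over the extended span;
4. colinear groups on nearby diagonals (within `band`, default 50) are merged
   with a banded global alignment (match +1, mismatch −1, gap −2) — the indel
   case; with the default substitution-only simulations this path is idle,
   and indel-containing homologies from other sources are otherwise reported
   as split gapless segments, like ungapped BLAST;
5. identity = matches / alignment columns (gap columns included).

**Boundary scoring.** The extension/trim scoring uses match +1 and mismatch
−t/(1−t), where `trim_break_even` t defaults to 0.5 and each detector sets it
just below its identity threshold (e.g. 0.8 for dispersed repeats at
min identity 0.90, 0.6 for transfer fragments at 0.70). The break-even
identity of the scoring then matches what the detector is asked to find:
boundaries neither bleed into flanking random sequence (which would dilute a
0.95-identity repeat below a 0.90 filter) nor clip the mismatch-rich ends of
a legitimately low-identity fragment.

**E-values.** Karlin–Altschul with the +1/−2 raw score the reports carry
(`score = matches − 2·(columns − matches)`), λ solved numerically from the
identity ∑ pᵢpⱼ e^{λ sᵢⱼ} = 1 at uniform composition and K = 0.621 (the
standard tabulated ungapped value for +1/−2), with search space = product of
total genome lengths. A consequence worth knowing: an exact match of ~27 bp
sits right at the E ≤ 1e-5 floor when two ~300 kb genomes are compared —
the same behaviour BLASTN shows — so the shortest confidently detectable
dispersed repeats are ~28–30 bp at that scale, and low-identity fragments
must be long (a 500 bp fragment at 70% identity scores 50, comfortably
significant; a 100 bp one scores 10 and is indistinguishable from chance).

# Read recruitment

`select_candidates()` marks a read as a candidate when some local match to a
conserved core gene is longer than 50 bp. `choose_seed()` ranks candidates by
(number of distinct core genes matched, total identity-weighted matched bp),
with a deterministic tie-break on read id; `cover = TRUE` greedily keeps
candidates that add an unseen core gene, because a multichromosomal genome
cannot be recruited from a single seed — each chromosome needs an anchor.
`recruit_iteratively()` then adds, per iteration, any unrecruited read
overlapping a recruited read by ≥1,000 alignment columns at ≥70% identity,
to a fixpoint (or `max_iter = 50`, a cap the procedure in practice never
reaches — the defaults converge in a handful of iterations). Matching is
incremental against the newly added reads only, so results are independent
of insertion order. "Overlap" means the matched alignment span, not a
dovetail: contained reads are legitimate recruits.

# Codon usage

`count_codons()` tallies sense codons and stop codons separately; by default
duplicated CDS sequences are counted once ("unique CDSs"), with
`unique_cds = FALSE` to count all gene copies — both conventions exist in the
literature and published totals rarely say which was used. `rscu()` is the
classic relative synonymous codon usage (family mean exactly 1; single-codon
families Met and Trp have RSCU 1 by definition — a published RSCU of 3 for
AUG is not reproducible under any standard definition and is not reproduced).
`effective_number_of_codons()` is Wright's estimator
Nc = 2 + 9/F̄₂ + 1/F̄₃ + 5/F̄₄ + 3/F̄₆ with F̂ = (nΣp² − 1)/(n − 1) per
family; the 6-fold families (Leu, Ser, Arg) go to the F̄₆ term; a degeneracy
class with no estimable family (n ≥ 2 and F̂ > 0) takes the mean of the
estimable classes (Wright's convention); the result is clamped at 61.
`start_stop_summary()` weights per-gene start/stop codons by copy number and
resolves edited-stop annotations like `"CGA(TGA)"` to the post-editing codon.

# RNA editing

`classify_edit()` validates that an edit is pure C→U (one or two C→T
positions per codon; the 5′-most position is reported for double edits, with
`n_edited_bases` carrying the count) and labels the amino-acid transition
with the two-class hydrophobicity map: hydrophobic = {A, I, L, F, M, P, V,
W}, hydrophilic = the other twelve. This is the unique two-class partition
consistent with the conventional labelling of plant mitochondrial editing
transitions (P→S as hydrophobic→hydrophilic, S→L as hydrophilic→hydrophobic,
H→Y as hydrophilic→hydrophilic, and so on); stop gains (only reachable from
hydrophilic codons via C→U) form their own class.

`predict_edit_sites()` is a reference-protein comparative predictor: the
translated CDS is globally aligned to each reference protein (identity
scoring, affine gaps 1/−1/−2/−0.5), a per-codon consensus is taken, and at
mismatching codons the minimal C→T edit(s) at positions 1–2 whose translation
matches the consensus are proposed, accepted at reference support ≥ 0.5.
Silent (position-3) edits are invisible to any protein-comparison method and
are never proposed; recall statements therefore exclude them. Per-position
summaries are reported as computed — published per-position splits for this
class of data can be internally inconsistent, and we do not force agreement.

# Repeats

* **Microsatellites** (`find_ssrs()`): maximal perfect runs of 1–6 bp units
  with MISA minima 1-10 2-5 3-4 4-3 5-3 6-3; motifs that are repetitions of a
  shorter unit are reported at the shortest unit; only complete units count
  (a maximal run phase-shifts by up to one unit when a flanking base happens
  to extend it — truth comparisons must allow that). `canonical_motif()`
  renders the class as the lexicographic minima over rotations of the motif
  and of its reverse complement ("AC/GT", "AAAC/GTTT", self-complementary
  "AT/AT"). Circular chromosomes are scanned with an origin window and wrap
  hits deduplicated.
* **Tandem arrays** (`find_tandem_repeats()`): candidate periods 7–120 bp
  scored position-against-previous-copy with the TRF match/mismatch weights
  (+2/−7) as maximal scoring segments; `percent_match` is the adjacent-copy
  agreement; arrays better explained by a 1–6 bp period are dropped (they are
  SSRs); `min_score = 50` (the TRF minscore) suppresses the ~6%-per-kb rate
  of chance 7 bp adjacent duplications in random sequence; overlapping
  reports keep the best-scoring period; copy numbers are fractional to one
  decimal. Indel moves are not implemented — the generator's imperfect
  arrays are substitution-only, and that is the regime the scores are
  validated in.
* **Dispersed repeats** (`find_dispersed_repeats()`): word-size-7 seeded
  self-comparison within and between chromosomes, both strands; the trivial
  self-diagonal and mirror duplicates are excluded; hits ≥80% covered by a
  supplied tandem/SSR interval set are excluded ("remove tandem
  duplication"); filters are length ≥ 27 bp, identity ≥ 0.90, E ≤ 1e-5. The
  27 bp default matches the smallest dispersed repeats such genomes are
  reported to carry, and sits at the statistical detection floor described
  above.

# DNA transfer and synteny

`find_homologous_fragments()` screens genome pairs at the conventional MTPT
thresholds (identity ≥ 0.70, length ≥ 30 bp, E ≤ 1e-5). `merged_coverage()`
merges overlapping query intervals before summing, so nested or duplicate
subject hits cannot double-count; because published "combined length" figures
rarely say whether they merged, the unmerged sum is also reported.
`genes_fully_contained()` reports genes whose full span lies inside a single
merged homologous region, with the best containing fragment's identity.
`synteny_blocks()` exports fragments ≥ 300 bp with orientation labels for
dot-plot/collinearity rendering, using a larger seed (k = 13) since blocks
are long.

# Molecular evolution

`ng86_kaks()` implements Nei–Gojobori (1986): per-codon synonymous site
fractions (changes to stops count as nonsynonymous; S + N = 3 per codon),
pathway-averaged difference counting over all orderings of the differing
positions with stop-passing pathways excluded (all pathways used if every one
is blocked), and Jukes–Cantor correction with proportions ≥ 3/4 flagged as
undefined. Gap/ambiguity codon columns are excluded pairwise, shared trailing
stops stripped, internal-stop columns excluded with a warning. The lookup
tables are verified against an independent recursive pathway enumeration over
all 61×61 sense-codon pairs in the test suite.

NG86 was chosen over ML counterparts because it is deterministic and
oracle-checkable. On neutral data it carries a small downward bias: with pure
uniform substitution at 0.04/site/lineage on 10 kb, the mean ratio over ten
replicate pairs measures ≈ 0.93–0.96 (stop-column exclusion and multi-hit
saturation push it further below 1 as divergence grows) — within the ±0.1
band used in validation, and the reason validation runs in this
low-divergence regime with replicate averaging rather than on single pairs
(a single 10 kb pair has ≈ 5% sampling error).

`nucleotide_diversity()` is Nei's π = 2/(n(n−1)) Σ d/L over pairs, with
pairwise deletion by default and complete deletion as an option — reference
implementations differ in their default and the choice moves π whenever
gaps are unevenly distributed.

# Pipeline and problem sizes

`run_pipeline()` orchestrates the stages in dependency order (repeats are
detected before tandem exclusion is applied to dispersed hits; transfer after
genome construction), writes TSVs per stage, and cross-checks the summary
against stage aggregates at build time. Configurations round-trip through
YAML.

The validation suite runs at deliberately modest sizes chosen so the whole
battery completes in about a minute: a 10-chromosome, ~300 kb genome for
planted-repeat and transfer recovery; a 3 + 3 chromosome, ~150 kb mixed pool
at depth 20 (≈ 300 reads of ~10 kb) for recruitment; 10 kb codon sequences
for the neutral Ka/Ks check. These sizes are large enough that every
detector's thresholds, not its luck, determine the outcome.

# Known limitations

* Substitution-only defaults: indel-rich reads split recruitment overlaps at
  indels, and the tandem scorer has no indel moves.
* The editing predictor shares the blind spots of all protein-comparison
  methods: silent edits, edits in non-coding regions, and U→C editing are out
  of scope.
* E-value calibration assumes uniform base composition; strongly skewed
  genomes shift the effective significance of short matches.
* The simulator's i.i.d. background understates the low-complexity and
  repeat-family structure of real plant mitochondria; measured recovery rates
  are upper bounds for field performance.
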