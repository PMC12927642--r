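---
title: "Screening bacterial genomes for oxalate metabolism toolkits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening bacterial genomes for oxalate metabolism toolkits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxascreen)
```

## The problem

Oxalotrophy — the ability of bacteria to use oxalate as a carbon and energy
source — matters for carbon cycling: the oxalate–carbonate pathway converts
plant-derived oxalate into CO~2~ that precipitates as calcium carbonate, a
stable inorganic carbon pool, while the assimilation route channels oxalate
into carbohydrate and amino-acid metabolism. Whether a strain can do either
is largely a question of which enzymes its genome encodes. `oxascreen`
implements a genome-to-phenotype screen for this trait: detect a catalogue
of 19 oxalate-metabolism enzymes plus the oxalate:formate antiporter in
bacterial proteomes, call each strain's pathway completeness, and, where a
predicted oxalotroph fails to grow on oxalate, look for protein-level
substitutions in the key enzyme that may explain the false positive.

## The screen

### Catalogue and reference database

The unit of detection is an *enzyme class*: an EC number (or the literal
`OxlT`) with one or more curated reference protein sequences. The bundled
catalogue has 20 classes. Two toolkits are singled out:

* **biomineralization** — oxalyl-CoA decarboxylase (Oxc, EC 4.1.1.8),
  formyl-CoA transferase (Frc, EC 2.8.3.16), and the antiporter OxlT;
* **assimilation** — glyoxylate carboligase (Gcl, EC 4.1.1.47),
  hydroxypyruvate reductase (EC 1.1.1.29), and serine–glyoxylate
  transaminase (EC 2.6.1.45).

A strain is called complete for a toolkit iff every member class is present
(at least one gene copy); completeness is deliberately binary — copy number
is reported but never thresholded. Catalogue contents are data: the last
two of the 20 bundled entries (EC 6.2.1.8, EC 1.1.1.26) are placeholder
choices rounding out the enzyme set, and a production screen should supply
its own curated table and reference FASTA. The bundled reference FASTA is
**synthetic** (deterministic random proteins, one or two per class); it
exists so the workflow, its tests and this vignette run without downloads,
and it is exactly as good as real references for validating the machinery
against planted ground truth — but detections against it say nothing about
real proteomes.

### Hits and the four-way filter

Each reference is aligned against each strain protein with affine-gap local
alignment (BLOSUM62, gap open 11, gap extend 1). Raw scores are rescaled to
bitscores with the standard Karlin–Altschul transform
$S' = (\lambda S - \ln K)/\ln 2$, using the published gapped-search
constants for this scheme ($\lambda = 0.267$, $K = 0.041$), and E-values are
$E = mn\,2^{-S'}$ with $m$ the reference length and $n$ the *total residue
count of the screened proteome* — the search space is per-strain, matching
per-genome screening semantics, and is recomputed for every proteome. A hit
must clear all four thresholds (all bounds inclusive, ties kept to favour
sensitivity):

| statistic | bound |
|---|---|
| E-value | ≤ 1e-3 |
| bitscore | ≥ 40 bits |
| percent identity | ≥ 30 % (identical columns / all gapped columns) |
| query coverage | ≥ 60 % (aligned reference span / reference length) |

Coverage comes from the single best local alignment — there is no HSP
tiling — and a protein matched by references of several classes counts
toward each (raw-hit semantics, no best-class assignment), while several
references of one class matching one protein count as a single gene copy.
`X` residues score 0 against everything, tolerating annotation artifacts
without inventing similarity; all other ambiguity codes are rejected with a
position. The alignment engine reports one optimal alignment
deterministically (DP traceback order breaks ties); every test asserts
scores and statistics rather than which co-optimal alignment is shown.

### From hits to biology

Filtered hits become a strains × classes copy-number matrix, its presence
view (copy ≥ 1), per-genus occurrence percentages, and toolkit calls with
Venn-style overlap counts for a focal genus (default *Pseudomonas*) versus
the rest. Classes are also grouped by prevalence with an exact 1-D k-means
(dynamic programming over sorted prevalences — optimal and deterministic,
unlike seeded Lloyd iterations), defaulting to k = 3 to mirror the
ubiquitous / intermediate / rare gradient typical of such screens; with
tied prevalences, membership follows catalogue column order.

### Substitution analysis

For a key enzyme (Gcl by default) the screen compares protein sequences
between oxalate-positive and oxalate-negative strains. Each strain's best
matching protein is globally aligned to a designated reference strain (a
star alignment — deterministic and adequate for closely related orthologs;
an externally computed aligned FASTA can be imported instead). A position is
*group-discriminating* iff every negative strain differs from the reference
there and every positive strain matches it. Substitutions are classified as
conservative iff their BLOSUM62 score is non-negative — a standard,
deterministic operationalisation of "biochemically similar replacement"
(I↔V scores +3: conservative; A↔D scores −2: non-conservative). The summary
counts unique (position, from, to) events, so a substitution shared by all
negative strains is one event. Insertions and deletions relative to the
reference are logged but are not substitutions.

### Genome context tree

For cohort context the package sketches genomes with bottom-s MinHash over
canonical k-mers (k = 21, s = 10000 by default, the conventions of the
ecosystem's sketching tools; s = 1000 is ample at the 50 kb simulated
genome size). The hash is splitmix64 over the 2-bit-packed canonical k-mer,
masked to 53 bits so every value is exactly representable as an R double —
a fixed, documented choice that keeps sketches byte-reproducible across
platforms. The Jaccard index is estimated from the bottom-s of the merged
hash union (the unbiased sketch estimator, not raw intersection/union), and
the Mash distance is $d = -\tfrac{1}{k}\ln\frac{2j}{1+j}$, capped at 1.0
when no hashes are shared. Trees are built by neighbor joining (negative
branch lengths clamped to zero) and exported as Newick with quoted labels
where needed.

## The synthetic cohort: what it does and does not emulate

Real screens run on hundreds of downloaded, annotated genomes; the
generator replaces that with a cohort whose *statistical structure* the
pipeline assumes, plus a truth manifest for exact scoring. Defaults — the
study conditions used throughout the tests and the acceptance script — are:

* 30 strains over 5 genera with a *Pseudomonas*-heavy skew
  (10/8/5/4/3), mirroring the composition bias of arid-soil culture
  collections;
* per-class presence probabilities chosen once to echo the biology the
  screen targets: core assimilation-pathway enzymes common (0.9),
  the biomineralization toolkit and the serine–glyoxylate transaminase
  rarer (0.35–0.4), biosynthesis enzymes rare (0.3);
* planted homologs are mutated copies of reference fragments at target
  identity 40–95 % (±2 points, acknowledging sequence discreteness) and
  target coverage 70–100 %, 1–3 copies when present, with short random
  flanks;
* 50 decoy proteins per strain drawn from proteome-wide residue
  frequencies; any decoy able to reach the filter's bitscore floor against
  any reference is discarded and resampled, and planted homologs are
  likewise resampled if they cross-match another class — so manifest zeros
  are true zeros;
* all *Pseudomonas* strains share one Gcl sequence; the last two carry
  three planted substitutions (A→D and G→W non-conservative, I→V
  conservative) and form the oxalate-negative group;
* 50 kb genomes from one simulated ancestor at per-strain mutation rates
  0 / 0.01 / 0.05 / 0.1 per site.

Passing on this cohort shows the machinery is correct — the filter, the
statistics, the counting rules, the group logic — under conditions where
truth is knowable. It does **not** show that the thresholds are well-tuned
for real proteomes: synthetic decoys lack paralogs, repeats, domain
shuffling and compositional bias, planted homologs have no indels, and the
synthetic references are not real enzymes. Margins observed here (e.g. a
planted 40 %-identity homolog comfortably clearing the 30 % floor) will be
thinner on real data.

## Numerical and design choices

* **Inclusive thresholds.** "E-value 1E-3" is read as ≤, and the other
  bounds as ≥, so boundary hits pass — ties favour sensitivity.
* **Per-proteome search space.** E-values are comparable within a strain
  and reproducible strain-by-strain; they are not corpus-wide.
* **Empty local alignments.** When no cell scores positively the aligner
  returns raw score 0 with an empty span; coverage is 0 and the pair can
  never pass the filter.
* **Exact 1-D clustering.** Prevalence clustering uses the dynamic-
  programming optimum; no random restarts, no seed sensitivity.
* **Degenerate inputs.** Empty proteomes warn and yield zero rows rather
  than failing the cohort; strains without genus metadata group under
  "Unassigned"; genomes shorter than k give empty sketches at distance 1.0
  from everything.
* **Determinism contract.** Every stage is a pure function of inputs and
  config; run manifests embed no clock values, and reruns are
  byte-identical. The generator's only entropy source is the mandatory
  seed.
* **Problem sizes.** The test suite and the acceptance script exercise the
  aligners exhaustively on all sequence pairs up to length 3 over a
  4-letter alphabet plus seeded random pairs up to length 12 (longer
  exhaustive enumeration grows as 4^2L and adds no new code paths), the
  full 30-strain cohort for planted-truth recovery, and 50 kb genomes for
  the distance stage — sizes chosen to probe every rule while keeping the
  whole analysis reproducible on a laptop.

## Worked example

```{r example, eval = FALSE}
cfg <- cohort_config(seed = 1)
sim <- generate_cohort(cfg, dir = "results/cohort")
generate_genomes(cfg, dir = "results/cohort")

res <- run_screen("results/cohort/proteomes", "results/cohort/metadata.tsv",
                  "results/run",
                  substitution_spec = list(
                    class_id = sim$manifest$gcl_class,
                    reference_strain = sim$manifest$reference_strain,
                    groups = sim$manifest$groups),
                  genome_dir = "results/cohort/genomes",
                  tree_s = 1000L, seed = 1)

# the screen's calls equal the generator's intent
all(res$toolkit_calls == sim$manifest$toolkit_calls)
res$overlaps
res$substitutions$summary
```

The same stages are available as numbered drivers under `analysis/`
(`01_simulate.R` … `06_tree.R`), each a thin narrative script over these
functions writing under `results/`.

## Known limitations

* The full-sensitivity search aligns every reference against every protein
  (no k-mer seeding); it is meant for cohorts of hundreds of strains, not
  millions of proteins.
* Star alignment to one reference can misplace substitutions near indels;
  for distant orthologs import a proper MSA via `read_aligned_fasta()`.
* The conservative/non-conservative rule is a matrix-sign convention;
  physicochemical-class schemes would label a handful of pairs differently.
* Toolkit completeness is a genomic hypothesis, not a phenotype: the
  substitution stage exists precisely because a complete toolkit can fail
  functionally.
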