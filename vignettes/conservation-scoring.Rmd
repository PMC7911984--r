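---
title: "Per-base conservation scoring and gene drive target ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Per-base conservation scoring and gene drive target ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conscore)
```

## The problem

CRISPR/Cas9 homing gene drives spread an engineered allele through an insect
population by cutting the wild-type allele at a guide-RNA-defined target
site. Any standing or induced variation at that site that blocks cleavage
while preserving gene function creates drive-resistant alleles, so target
sites should be chosen in sequence under strong functional or structural
constraint. Sequence conservation — across related species and within the
target species' own populations — is a practical proxy for such constraint.

`conscore` turns three observable signals into a single per-base
conservation score over a reference genome:

1. **Interspecies identity.** Pairwise whole-genome alignments of m query
   species against the reference are scanned with sliding windows; windows
   whose identity clears a threshold become conserved elements, projected
   back onto the reference at per-base resolution.
2. **Intraspecies variation.** Segregating sites from population resequencing
   (a VCF) are converted into a windowed SNP density: variation within the
   species argues directly against targeting that base.
3. **Per-site selection.** An externally computed conservation/acceleration
   score track (phyloP-style CONACC convention: positive values mean slower
   than neutral substitution, negative mean faster) modulates the result.

## The model

For chromosome position $n$ and species $i$ with per-base identity
$I_{i,n} \in [0,1]$ and patristic distance $d_i$ to the reference:

$$
\mathrm{Cs}_n \;=\;
\frac{1}{m}\sum_{i=1}^{m} I_{i,n}\, d_i
\;\times\;
\frac{1-\sigma_n}{1+\sigma_n}
\;\times\;
2^{\,p_n}
$$

with $\sigma_n$ the SNP density in a 20-bp window centred on $n$ and $p_n$
the selection score. Raw scores are MinMax-scaled to $[0,1]$ per chromosome
arm, so 1 marks the arm's most conserved base.

Reading the three factors:

* **Distance weighting** ($I_{i,n} d_i$). Identical sequence in a
  phylogenetically distant species is much stronger evidence of constraint
  than in a sibling species, so identity is multiplied — not divided — by
  distance. Because MinMax scaling absorbs any global factor, only the
  *relative* distances matter; rescaling the whole distance vector leaves
  the scaled track unchanged (this is asserted as a package invariant).
* **Averaging over all m species.** The mean runs over every configured
  species, with species lacking an aligned element at $n$ contributing 0.
  This keeps scores comparable along the chromosome and penalises sequence
  that fails to align at all — no alignment, no conservation evidence.
* **SNP penalty** $(1-\sigma)/(1+\sigma)$: equals 1 when no variation is
  observed, 0 when every base in the window segregates, and decreases
  strictly in between. $\sigma$ is a fraction, not a count: the factor is
  only self-consistent on $[0,1]$ and the window span is its denominator.
* **Selection factor** $2^{p}$: neutral sites ($p=0$) are unchanged,
  conserved sites ($p>0$) are boosted, accelerated sites ($p<0$) are
  damped. Together with finite $p$ this keeps $\mathrm{Cs}_n \ge 0$.

## The identity scan

Windows are anchored on **reference coordinates**: a 30-bp window always
covers 30 reference bases, whatever gaps the alignment carries, so detected
elements project exactly onto the reference. Within a window, a position
counts as a match only when reference and query bases are identical and
both are unambiguous A/C/G/T — a reference base aligned to a gap or to N is
a mismatch, and query insertions occupy no reference coordinate. Windows
never span two alignment blocks.

The default configuration runs two scans — thresholds 90/97/100% over 30-bp
windows and 70/90/96/98/100% over 50-bp windows (a 98% identity 50-bp
window is exactly 49 matching positions) — with a global floor of 70%
identity. Within one (window, threshold) scan, *overlapping* qualifying
windows are merged into maximal runs; each run reports the maximum window
identity inside it. Abutting runs are kept separate. All scans are then
pooled by taking, at every base, the maximum identity over all elements
covering it — this projection makes the final matrix insensitive to how
individual scans chop runs, which is why it was chosen.

## Phylogenetic distances

Distances are patristic: the sum of branch lengths along the unique tree
path between the reference leaf and each species' leaf, computed from a
user-supplied Newick tree. When no tree is available, a Jukes–Cantor (JC69)
fallback estimates each distance from the alignments themselves,
$d = -\tfrac{3}{4}\log(1-\tfrac{4}{3}\hat p)$ with $\hat p$ the mismatch
fraction over aligned ungapped unambiguous sites; $\hat p \ge 0.75$ is
reported as saturation rather than a number. When both are given, the tree
wins: a fitted substitution model is more defensible than the one-parameter
fallback.

## Target sites

An SpCas9 target site is the canonical 23-bp unit: a 20-nt protospacer
followed by an NGG PAM on the site's own strand. Enumeration scans both
strands (`GG` at site positions 22–23 on the plus strand; `CC` at positions
1–2 of the plus-strand window for minus-strand sites); sites containing N
or truncated by the region boundary are dropped. Each site gets the mean,
minimum and maximum of the scaled score over its 23 bases, and an
accessibility flag: any overlap with the accessibility mask (low-complexity
or poorly genotyped intervals) marks the site inaccessible, but such sites
are *flagged, not removed* — apparent ultraconservation inside masked
repeats may reflect alignment artefacts or concerted evolution rather than
constraint, and should be read cautiously rather than silently discarded.
Ranking is by mean score, ties by minimum score, then coordinates, making
the order deterministic and input-order-invariant. Percentiles of a score
are computed against the arm's *positive* scaled values only, since the
zero class is dominated by unalignable sequence.

Published site tables print 1-based inclusive coordinates, so the exported
target table writes a 23-bp site as, e.g., `48714594 48714616`; internally
every coordinate is 0-based half-open, converted only at file boundaries.
This single-convention rule also fixes the AXT reader (1-based inclusive on
disk) and the bedGraph/BED writers (0-based half-open on disk).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `windows` | 30, 50 bp | identity scan window lengths |
| `thresholds` | 90/97/100% and 70/90/96/98/100% | per-window identity cutoffs |
| `min_identity` | 0.70 | global floor; nothing below it is reported |
| `snp_window` | 20 bp | SNP-density window, centred, end-truncated |
| `scaling` | `arm` | MinMax domain; `genome` pools arms (differences are negligible in practice) |
| `fill` | 0 | selection score for positions absent from the track (neutral) |

## Numerical and degenerate-input choices

* MinMax on a constant domain maps to all zeros with a warning: a flat raw
  track carries no conservation contrast, and 0 ("no evidence") is the
  conservative reading.
* Threshold comparisons use a `1e-9` slack so that, e.g., 49/50 compared
  with 0.98 is not lost to floating-point representation.
* The even SNP window covers offsets $[-w/2, w/2-1]$ around the focal base;
  truncated end windows use their actual span as denominator.
* Overlapping records in a score track are resolved last-record-wins, with
  a warning — deterministic and detectable.
* A multi-allelic VCF record contributes one position; duplicates collapse.
  By default only single-nucleotide records count (`snps_only = TRUE`);
  indels can be included with a flag.

## The synthetic study system

The generator builds a fully self-contained system with known ground truth:
a uniform-random reference arm (default 100 kb); six query species diverged
along a fixed tree at reference distances 0.05–0.48 substitutions/site,
each site substituted independently with the JC69 probability
$p(t) = \tfrac{3}{4}(1-e^{-4t/3})$; three embedded ultraconserved blocks
(about 1.5% of the arm) copied verbatim in every species and excluded from
SNPs; Bernoulli population SNPs at 1% per base elsewhere; a selection track
of +1.5 inside blocks and 0 outside; and a mask covering about 5%, drawn
away from the blocks. Every stage derives its random stream from the single
seed, so the whole bundle is byte-reproducible.

These defaults were chosen once as a realistic desk-scale analogue of a
mosquito-complex study: distances span sibling species through saturating
divergence while staying in the range where JC69 recovery is testable
($t \le 0.5$), and 1% SNP density reflects the very high diversity seen in
large wild-caught resequencing panels. Test problem sizes (20–100 kb arms,
six species, five seeds for stochastic checks) are the package's own
choice of smallest sizes at which the statistical assertions have power.

What the generator deliberately omits: rearrangements and indels (each
species is one collinear alignment block, so the scan's within-block
behaviour is exercised but synteny breaks are not), richer substitution
models than JC69, coalescent population structure, and genotype-level
variant information. Passing tests therefore demonstrate the pipeline's
arithmetic and ranking behaviour, not robustness to alignment artefacts in
real assemblies.

One interaction worth knowing: because close species (t ≈ 0.05) exceed the
70% identity floor almost everywhere, their merged elements can span most
of the arm and carry identity 1.0 after per-position pooling — synthetic
close-group identity tracks are therefore near 100%, higher than real
sibling-species tracks where unalignable sequence breaks runs. Distance
recovery with JC69 is assessed on block-free simulations, since
ultraconserved blocks deflate realised divergence below the nominal branch
length by construction.

## A worked example

```{r example, eval = FALSE}
library(conscore)

cfg <- sim_config(seed = 1)                  # 100-kb arm, 6 species
ref <- simulate_reference(cfg)
sim <- simulate_species(ref, cfg)
snps <- simulate_population_variants(ref, cfg)
sel <- simulate_selection_track(cfg)

elements <- scan_conserved_elements(sim$blocks)
I <- project_identity(elements, ref, "chr1", species = sim$distances$species)
track <- conservation_score(
  normalize_identity(I, sim$distances),
  sigma = snp_density(snps$pos, 100000),
  phylop = sel$chr1) |>
  minmax_scale()

glance(track)
sites <- enumerate_cas9_sites(ref, "chr1") |>
  score_sites(track, simulate_mask(cfg)) |>
  rank_sites(top_k = 10)
autoplot(track)
```

The same flow over files (FASTA/AXT/Newick/VCF/bedGraph/BED in, BED,
bedGraph and ranked TSV out) is `run_pipeline(pipeline_config(...))`, or
the `inst/cli/conscore.R` script from a shell.

## Known limitations

* Alignment production (LASTZ, chaining/netting) and selection-score
  computation (phyloP model fitting) are upstream of this package: it
  consumes their outputs and, for testing, emulates them synthetically.
* The per-base identity matrix is dense in memory (m × arm length doubles);
  chromosome-scale mosquito arms fit comfortably, but very large genomes
  would need a chunked backend.
* The JC69 fallback ignores rate variation and is biased downward when
  truly invariant blocks are embedded in the alignment.
* Elements are not restricted to noncoding sequence; coding-region identity
  is intentionally retained, since gene drive targets are typically genic.
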