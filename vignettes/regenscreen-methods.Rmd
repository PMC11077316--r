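---
title: "Methods: the conservation screen and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the conservation screen and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`regenscreen` asks a phylogenetic-profiling question: which gene families are
conserved in every whole-body-regenerating (WBR) species and absent from
every low-regenerative-ability (LRA) species? This vignette documents the
model behind each stage, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices a maintainer would want spelled out.

## 1. The similarity engine

All sequence comparison is exact Smith–Waterman local alignment with affine
gaps: a gap of length $L$ costs `gap_open` $+ L \cdot$ `gap_extend`
(defaults 11 and 1), scored with BLOSUM62. Non-canonical residues (`X` and
anything else outside the 20-letter alphabet) score $-4$, the matrix
minimum, so unknown residues can never manufacture similarity. Exactness
replaces heuristic seeded search deliberately: at the scale this package
targets, exact alignment is affordable and removes seeding as a confound;
for full-scale data, externally computed BLASTP tabular output (outfmt 6)
can be ingested through `read_hits_tsv()` and drives the identical
downstream operations.

Raw scores become E-values through the Karlin–Altschul form
$E = K\,m\,n\,e^{-\lambda S}$, where $m$ is the query length and $n$ the
summed length of the subject species' isoform-reduced proteome (the BLAST
database-length convention). **Calibration of $K$ and $\lambda$.** These are
calibration constants, not fitted statistics of any particular search. The
shipped defaults ($K = 0.045$, $\lambda = 0.22$) were derived by simulating
the package's own null — gapped BLOSUM62/11/1 alignment of
uniform-composition random protein pairs at lengths 250–500 — and fitting
$\log P(S \ge s) = \log K - \lambda s$ to per-cell exceedance rates
(`calibrate_evalue_constants()` reproduces the experiment). The global fit
gives $K = 0.045$, $\lambda \approx 0.229$; we adopt the slightly flatter
deep-tail estimate $\lambda = 0.22$ because threshold decisions happen far
in the tail (scores near 100), where underestimating the chance-hit rate
would make the loss filter spuriously remove true candidates. Textbook
BLAST constants assume database residue composition and would understate
$E$ here by roughly two orders of magnitude at the decision threshold.
Because every screen decision depends only on threshold *ordering*, the
calibration shifts which raw score corresponds to $E = 10^{-4}$ but not the
logic of any stage.

## 2. The screen

1. **Isoform reduction.** One sequence per gene: a maximal-length isoform,
   ties broken by smallest isoform id (determinism).
2. **Orthology.** Mutual best hits per species pair; "best" is max score,
   then min E-value, then lexicographically smallest subject gene. The
   tie-break hierarchy is a package convention chosen purely for
   determinism.
3. **Orthogroups.** The default rule demands an MBH *clique* across all WBR
   species (for three species, triangle closure). The weaker alternative —
   connected components of the MBH graph with one member per species — is
   available as `grouping = "components"` for sensitivity analysis, since
   the multiway construction is genuinely underdetermined in this kind of
   screen.
4. **Loss filter.** Any-hit semantics: one hit at $E \le$ `evalue_max_loss`
   (default $10^{-4}$) anywhere in any LRA proteome disqualifies the group.
   We read "hits were not found" strictly, which makes the filter the
   stringent arm of the screen; best-hit-only semantics would retain more
   groups.
5. **Confirmation.** The same any-hit filter against a separate CONFIRM
   proteome panel, standing in for screening candidates against a
   comprehensive database; a per-group audit log records every removing
   hit. An empty panel warns and passes groups through.
6. **HRA collection.** For each surviving group, the anchor member (first
   configured WBR species) is searched against each HRA proteome; presence
   requires a mutual best hit **and** raw score strictly greater than
   `score_min_hra` (default 100). The mutual-best-hit requirement on top of
   the score threshold is a deliberate consistency choice with stage 2.

The loss filter's contract takes precomputed hit lists; the pipeline obtains
them with `scan_panel_hits()`, which scans members in species order and
panel genes in id order and stops at a group's first disqualifying hit.
Under any-hit semantics this early exit provably leaves the surviving set
unchanged while skipping most of the alignment work; the equivalence is
property-tested against full hit lists on small panels.

## 3. Gene trees

Candidate adjudication (ortholog vs diverged paralog) is a topological
question, so the package uses a deterministic distance pipeline rather than
maximum likelihood: progressive alignment (average-linkage guide tree on
pairwise score distances $1 - S_{ab}/\min(S_{aa}, S_{bb})$; profile–profile
global affine alignment with frequency-weighted column scores), pairwise-
deletion p-distances with the amino-acid correction
$d = -\tfrac{19}{20}\log(1 - \tfrac{20}{19}p)$ capped at 5, Saitou–Nei
neighbor joining with lowest-index tie-breaking and negative branch
estimates clamped to zero, and nonparametric column-resampling bootstrap
(default 100 replicates) with supports attached to the full-data tree's
internal bipartitions. `write_phylip()` exports alignments for external
maximum-likelihood runs when branch support of publication grade is needed.
`is_separated_cluster()` answers the adjudication question: does some
internal edge split the high-regenerative members exactly from the rest?

## 4. Promoter enrichment

JASPAR-format count matrices (with a sidecar TF-class table) are turned into
log-odds matrices against background base frequencies (default uniform)
after adding a total pseudocount of 0.8 per column split by background. A
window is a hit when its log-odds score reaches
`score_fraction_threshold` (default 0.85) of the achievable score range —
a rescaled-threshold convention in the style of classic PWM matchers.
Both strands are scanned; `N` contributes zero log-odds.

Enrichment is *gene-level*: a gene counts once if its window has at least
one hit, giving a 2×2 table of target vs background genes tested two-sided
with Fisher's exact test. `log2_enrichment` is the log ratio of hit
proportions; exactly equal proportions give 0, otherwise zero hit counts are
continuity-corrected to 0.5. Per window length (defaults 100, 500, 1000,
3000, 5000, 7500 bp) the ten records with smallest p (ties by largest
enrichment) are tallied by TF class — a ranked-enrichment summary, so no
multiple-testing correction enters the tally; BH-adjusted p-values are
emitted alongside for users who want significance statements.

**Calibration scenario.** The null check simulates target and background
promoters with *equal* motif plant rates and asks whether the fraction of
tests at $p < 0.05$ sits inside the 95% binomial envelope of 0.05. Two
design points matter. First, table sizes: Fisher's exact test is
conservative on small tables; a pre-registered size analysis (simulating
binomial 2×2 tables directly) showed that with 200 target and 600 background
genes and per-gene hit rates near 0.5 the finite-sample size is ≈ 0.05, so
the envelope check is meaningful. Second, the calibration panel is
restricted to matrices whose random-hit probability at the scenario's
1000 bp windows is moderate (the width-6 matrices of the shipped synthetic
set): a matrix that essentially never hits yields degenerate all-zero
tables with $p = 1$, and a test that cannot reject cannot have its
calibration assessed. Like any 95% envelope, the check itself has a ~5%
false-alarm rate.

## 5. Expression phases

Trajectories are summarized as log2 fold changes against the 0 h baseline
with a +1 pseudocount. Three windows operationalize the regeneration
timeline: early $(0, 6]$ h (wound response), mid $(6, 96]$ h (stem-cell
proliferation), late $> 96$ h (differentiation). The classifier applies, in
order: wound_response (early window reaches `fc_threshold`, default 1 log2
unit); late_arrested (mid window reaches it *and* the late window's mean
change returns within half the threshold of baseline); proliferative (mid
window reaches it); differentiation (only the late window reaches it);
flat. late_arrested precedes proliferative because an arrested trajectory
also satisfies the proliferative condition mid-course. These boundaries are
explicit, exposed operationalizations of narrative phase descriptions; they
are validated against synthetic truth only and make no claim of reproducing
any published per-gene call on real data. Replicate columns are averaged
before classification. `delta_delta_ct()` implements
$2^{-\Delta\Delta C_T}$ exactly and warns on cycle values outside [1, 45].

## 6. The synthetic-data generator

The generator emulates the statistical structure the screen assumes, not
realistic molecular evolution:

* Family ancestors are i.i.d. uniform over the 20 amino acids, lengths
  uniform on 120–600. Substitutions replace a residue with a uniform
  different one (no rate matrix, no site-rate variation); indels are rare
  single-residue events (default rate 0.005/site). The screen's decisions
  ride on score *gaps* between orthologs, paralogs and chance alignments,
  and those gaps do not need realistic substitution processes.
* Background families place one ortholog (species divergence, default
  0.1 substitutions/site from the ancestor) in every species. Planted
  candidate families exist in all WBR species and each HRA species with
  probability 0.7 (the realized subset is recorded as truth). Paralog
  families exist in all WBR species plus one LRA copy that retains a ≤ 120
  aa domain mutated at 3× the species divergence inside otherwise random
  sequence. The domain construction (rather than whole-sequence 3×
  divergence) keeps the paralog's best score *below every* ortholog pair's
  score regardless of family length — whole-sequence divergence would let a
  long paralog outscore a short family's orthologs — while keeping it far
  above the E ≤ 1e−4 line, so the loss filter, not the clique step, is what
  removes paralog families. The generator verifies this separation
  empirically and warns if violated.
* 15% of genes receive 2–4 isoforms (truncations, occasionally extended
  tails) to exercise the longest-isoform rule.
* Promoters are i.i.d. uniform ACGT with at most one planted motif copy at
  a uniform position and strand. Expression is a phase template (baseline
  10 FPKM, elevated windows at 4× baseline) with multiplicative lognormal
  noise.

What passing the end-to-end tests shows is therefore that the *inference
machinery* is correct under the screen's own assumptions — clean orthology,
score-separated paralogy, independent promoters. It does not show
robustness to real-data pathologies: compositional bias, domain shuffling,
lineage-specific duplications, annotation errors, or promoter sequence
structure. The default scenario (3 WBR, 5 HRA, 8 LRA, 2 CONFIRM species;
200 background + 10 candidate + 10 paralog families) was sized so the whole
pipeline runs in about two minutes on one core; all counts are free
parameters of `default_config()`.

One stochastic caveat is inherent to the screen itself: with the E-value
threshold at $10^{-4}$ and ~300 member-vs-proteome scans per run, the
expected number of chance disqualifying hits is ~0.01–0.03 even with
calibrated constants, so roughly one default-scenario run in fifty may lose
one planted family to a chance alignment. That is the designed behaviour of
the published threshold, not a defect of the implementation.

## 7. Determinism and seeds

Every stochastic operation takes an explicit integer seed. The pipeline
derives per-stage seeds by salting the global seed with the stage name, so
adding or removing one stage never changes a sibling stage's stream.
Reruns with an identical config produce byte-identical primary outputs
(property-tested). All orderings that could depend on hash or locale
vagaries are fixed by explicit lexicographic sorts.
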