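---
title: "Methods: from PBM probe intensities to motifs and composite-motif enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from PBM probe intensities to motifs and composite-motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmotif)
```

pbmotif implements the computational chain that turns protein binding
microarray (PBM) experiments into usable transcription-factor motif
resources: probe-level quality control and spatial de-trending, 8-mer
E-/Z-score statistics, PWM derivation and cross-array selection, motif
transfer by DNA-binding-domain (DBD) homology, collection-level clustering
and curation, and two families of downstream interpretation — stereospecific
composite-motif (CM) detection in ChIP-seq peak sets and motif enrichment in
yeast one-hybrid (Y1H) bait and promoter/gene-set collections. A synthetic
data module generates every input the pipeline consumes, with the
statistical structure the analysis assumes, so the whole chain is testable
without any external download. This vignette records the models, the
tunable constants, and the design choices made where the procedures were
genuinely open.

## Synthetic array designs and the intensity model

Universal PBM arrays achieve complete k-mer coverage via de Bruijn
sequences. `generate_design(order, probe_length)` builds, per design, an
independently randomized de Bruijn cycle of the requested order (a random
Euler circuit of the transition graph on (order−1)-mers) and chops it into
probes overlapping by order−1 bases, so every order-mer appears exactly once
across probe cores (single strand) and nothing is lost at junctions. It
follows that any k-mer with k ≤ order appears exactly 4^(order−k) times per
strand; at order 10 a non-palindromic 8-mer has 32 double-stranded
occurrences and a reverse-complement palindrome 16, which
`count_kmer_occurrences()` verifies directly on the cycle (so probe-overlap
regions are not double-counted). Real arrays of this type carry ~41,000
35-mer probes; the default synthetic order is 8 for desk-scale runs (order
10 takes a few seconds and is used where 8-mer statistics at realistic
coverage are needed). Probe-length must satisfy the chopping constraint that
`probe_length − (order − 1)` divides 4^order; defaults are chosen
accordingly (order 8 with 23-mers, order 10 with 41-mers). A fixed linker
suffix is not modelled: only the de Bruijn core carries coverage guarantees.

`simulate_intensities()` is the forward model used for testing:
intensity = baseline × (1 + `affinity_scale` × occupancy) × spatial bias ×
lognormal noise. Occupancy is the same Boltzmann occupancy the scoring
module uses (below), summed over strands and offsets; the bias field is a
smooth planar gradient with peak relative amplitude `spatial_amplitude`
(1 ⇒ a 2× corner-to-corner gradient); noise is multiplicative lognormal
with log-sd `noise_sd`. Defaults (`affinity_scale = 20`, `noise_sd = 0.1`,
i.e. ~10% spot CV) emulate a strong, clearly successful experiment — the
regime the success criteria are designed to detect. What the simulator does
*not* model: scanner saturation, antibody chemistry, probe secondary
structure, or position-of-site-within-probe effects; conclusions from
passing tests are therefore about the statistical machinery, not about
array chemistry.

## Probe processing and 8-mer statistics

Spots flagged `bad`/`suspect` are removed (`filter_probes()`), and
intensities are spatially de-trended with a 7 × 7 median window centred on
each spot: each intensity is divided by (local median ÷ global median), with
windows truncated at grid edges (`spatial_detrend()`). A median window
removes smooth gradients while leaving isolated bright spots — true signal —
essentially untouched. Edge truncation leaves a residual bias proportional
to the per-cell gradient; on grids of 64 × 64 and larger a 2× gradient is
flattened to within 2%.

Per 8-mer (canonical key: the lexicographic minimum of the word and its
reverse complement; palindromes are their own key):

* **E-score** (`compute_escores()`): a modified AUROC in [−0.5, +0.5]. The
  foreground is the set of probes containing the word on either strand; E is
  the Wilcoxon–Mann–Whitney AUROC between the *top half* of the foreground
  and the *top half* of the background, by intensity rank, minus 0.5. This
  top-half convention is the one used by the statistic's originating
  laboratory pipeline; the plain full-set AUROC−0.5 is available via
  `variant = "full"`. Rank ties are resolved stably by probe order —
  irrelevant in practice because intensities are continuous. E > 0.45 is
  treated as highly significant throughout.
* **Z-score** (`compute_zscores()`): the mean of log-transformed intensities
  over probes containing the word, median-centred and sd-scaled across all
  words, giving a distribution with median 0 and sd 1 by construction.
  Whether the original processing logged intensities first is not printed
  anywhere we could verify; log is the default here (`log_transform`
  toggles it), and mean aggregation can be switched to median.

E-score stability depends on probes-per-word: an order-m design covers each
m-mer once per strand, so 8-mer statistics behave like the real arrays only
at order 10 (32 probes per 8-mer). Desk-scale tests therefore score 6-mers
on order-8 designs — the same 32-probes-per-word regime — and the k = 8 /
order-10 combination is exercised where the claim genuinely concerns 8-mers.

An experiment pair (two array designs) **succeeds** (`assess_success()`)
when at least one word exceeds E 0.45 on both arrays, cross-array E and Z
correlations are high, and the two arrays' derived PWMs align well. The
correlation cutoffs behind "highly correlated" are not printed in any
source we reproduce; they are explicit configuration here (defaults
r_E = r_Z = 0.6, PWM similarity 0.8).

## PWM derivation, energy scoring, and selection

`derive_pwm_align()` stacks the top-10 words by E: the best word seeds the
alignment; every other word is placed at the ungapped offset/orientation
(overlap ≥ 6) maximising identity to the seed, ties toward smaller |offset|
then forward orientation; aligned base counts plus a pseudocount are
normalised, and flanking columns supported by fewer than half the words are
trimmed. Seed ties resolve lexicographically, making derivation fully
deterministic. Of the four derivation algorithms used in the original
compendium work only this alignment method is reconstructible from public
descriptions; the evaluation/selection harness accepts externally supplied
candidate PWMs so other fitters remain pluggable.

`energy_score_probes()` implements the Boltzmann occupancy convention of
energy-based PBM models: per-position mismatch energies
ε(i,b) = −ln(p(i,b)+pc) + ln(max_b p(i,b)+pc), site weight
1/(1+exp(Σε−μ)), summed over both strands and all offsets. The constants
(pc = 0.01, μ = 0) are not printed in the sources; they are configuration
defaults here, and scoring is exactly strand-symmetric.

Candidates are evaluated on the held-out array (`evaluate_pwm()`) by (1)
Pearson correlation of predicted scores with observed log intensities (raw
intensities via `log_intensity = FALSE`) and (2) the AUROC with which
predictions separate "bright" probes — probe-level intensity Z ≥ 4 — from
the rest. `select_best_pwm()` ranks candidates by the mean of the two
criterion ranks, breaking ties toward higher bright-probe AUROC and then
the shorter motif.

## Motif catalogue: homology transfer, clustering, curation

`dbd_percent_identity()` globally aligns DBD amino-acid sequences (BLOSUM62,
gap open 11 / extend 1; multi-domain proteins concatenated in order) and
reports identities over aligned columns excluding terminal gaps.
`infer_motifs_by_homology()` assigns each uncharacterised TF the motif of
its best same-class source at or above the class threshold — never chained
through intermediates and never across DBD classes. Documented thresholds:
NHR 70%, DM 85%; other classes use a conservative 70% default
(`family_thresholds()`), since the full per-class table lives in an
external compendium rather than in anything reproduced here.

`shared_8mer_fraction()` compares two experiments' top word sets (E > 0.45)
with the overlap coefficient, 100·|A∩B|/min(|A|,|B|) — the denominator is a
package choice, as the original "% shared" denominator is not defined.

`align_pwms()` scores motif similarity as an information-content-weighted
Pearson correlation between aligned probability columns (all offsets with
≥ 4 overlapping columns, both orientations; per-column weight = mean of the
two columns' IC, with a product alternative behind a flag). Uniform motifs
have zero IC everywhere; their similarity is reported as 0 with a warning
rather than an arbitrary correlation. `cluster_pwms()` runs average-linkage
hierarchical clustering on 1 − r and cuts at the deepest branches whose
average pairwise internal correlation reaches 0.8, emitting per-cluster
centroids (members aligned to the best-connected member and averaged
position-wise). The exact column search of the original clustering tool is
not fully published; equivalence with it is not claimed. Note that
"well-separated families" means across-family aligned r below ~0.3: because
similarity is maximised over offsets and orientations, even unrelated sharp
motifs typically reach r ≈ 0.5–0.7, and a branch mixing such families can
still satisfy the 0.8 average internally.

`curate_motifs()` encodes the deterministic curation cascade: experimental
over inferred; in-vitro over in-vivo; method rank PBM > B1H > SELEX (then
databases/predictions); preference for the cluster holding a strict
majority of the TF's motifs (ties confer no preference); preference for
candidates with positive enrichment support when supplied. Multiple motifs
survive only when the remaining candidates fall in different clusters —
distinct binding modes such as monomer and dimer forms — and the full
decision trace is attached to the result.

## Composite motifs

Motif matches use log-likelihood scoring, log2((p+pc)/0.25) summed over a
window, with matches at ≥ 0.50 × max_score; the log base and the inclusion
of the pseudocount in max_score are fixed here (base 2, included) because
the sources leave them unstated. A motif whose best unpseudocounted score
is non-positive (e.g. uniform) cannot support a relative threshold and is
rejected by the scanner. Match coordinates are 1-based, with minus-strand
matches reported at the plus-strand coordinate of their leftmost base.

A composite pattern is (arrangement, spacing): four stereospecific
arrangements of the ChIPed motif (1) and partner (2) — 1F2F, 1F2R, 2R1F,
2F1F — crossed with spacings −5..+10 (negative = overlapping instances),
64 configurations per pair; spacing is start(downstream) − end(upstream) − 1.
Counting is presence/absence per peak so the "≥ 10% of input peaks" filter
reads naturally (total occurrences behind `unit = "occurrences"`), and a
whole cassette on the minus strand counts toward the same canonical
arrangement — scans are exactly invariant to reverse-complementing every
peak. When a homodimeric pair is scanned (partner = ChIPed motif), 1F2F and
2F1F describe the same physical pattern and both are emitted.

`cm_scan()` assesses each configuration against two null models: ten
dinucleotide-preserving shuffles of the peak sequences (an exact
Altschul–Erikson Eulerian-path shuffle conserving the 16-bin dinucleotide
counts and terminal bases), or ten column-shuffles of the partner motif
scanned over the original peaks. The motif-shuffle null over-calls patterns
whose constituent motifs overlap — shuffling disperses the adjacent
high-information core columns — so the sequence shuffle is the default
reported model, with the motif shuffle retained for concordance checks.
z = (observed − mean(null))/sd(null) with an sd floor of 0.5 counts (ten
replicates make a zero sd otherwise possible; the floor is noted whenever
applied); p is the upper normal tail of z — the sample-z-and-p convention
over ten replicates implies a normal approximation — and Bonferroni
multiplies by the full enumeration size of the run (e.g. a 77-peak-set ×
129-partner scan tests 635,712 patterns). A pattern passes with count ≥ 10%
of peaks and corrected p ≤ 0.05. Family-level summaries use
OR = (a/b)/(c/d) with SE = √(1/a+1/b+1/c+1/d) and CI exp(ln OR ± 1.96 SE),
Haldane-correcting zero cells. `build_cm_logo()` stacks the actual matched
cassettes (canonical orientation) into base-count matrices for logos.

The synthetic peak generator plants cassettes sampled from the two PWMs at
a chosen configuration into dinucleotide background. With negative spacing
the downstream instance's bases take precedence in the overlap — a
deterministic, documented convention matching the scanner's coordinates —
which means overlap planting *overwrites* part of the upstream site: for
incompatible consensus words the planted upstream motif no longer matches,
by construction. Recovery benchmarks therefore plant non-negative spacings.

## Enrichment statistics

`pwm_score_distribution()` computes the exact null distribution of the
log-odds window score by position-wise convolution on a discretized grid
(1/1000 of the score range; scanning uses the same per-position integer
scores, so scanner and null agree bit-for-bit on the grid, and
discretization only matters below that resolution). `scan_promoters()`
calls a gene a hit when any window on either strand of its promoter
(−500..+100 around the TSS, 601 bases) beats the exact p < 1e-4 threshold;
`geneset_fisher()` applies the one-sided hypergeometric test to hit/set
overlaps and `enrich_genesets()` controls FDR by Benjamini–Hochberg across
all motif × set tests in a run (the FDR procedure is not named in the
sources; BH is the package's choice throughout).

Y1H enrichment scores the promoter-proximal first 500 bases of each bait
with the occupancy model, compares positives against negatives with a
two-tailed Mann–Whitney U test (direction from the rank-biserial sign), and
refuses TFs binding fewer than five baits to avoid the sampling error of
tiny positive sets. `central_enrichment()` is a deliberately simplified
central-enrichment test and is labeled as such in its output: each peak
contributes its best-match midpoint and a one-sided binomial test compares
the central-window fraction against the uniform expectation over attainable
midpoints; there is no likelihood-ratio optimisation over window widths as
in the full CentriMo algorithm.

## Pipeline, determinism, problem sizes

`pbm_config()` centralises every constant (E cutoff 0.45, bright-Z 4, match
threshold 0.50, spacing −5..+10, 10 shuffles, 10% count filter, α 0.05,
cluster R 0.8, promoter p 1e-4 and window −500..+100, Y1H minimum 5 and
scan length 500, top-250 peaks, 7×7 detrend window). `run_pipeline()` chains
simulate → score → derive → cm → enrich on synthetic data, derives every
stage's seed from the master seed, and writes TSV/FASTA/MEME/JSON artifacts
plus a manifest (parameters, versions, checksums); repeated runs are
byte-identical. There are no hidden global RNG dependencies: every
stochastic function takes a seed.

Problem sizes used by the test suite are chosen to keep a full run at a few
minutes on one core while preserving the statistical regime of the real
study: order-8 designs (4,096 probes) scored at k = 6 for coverage-matched
word statistics, one order-10 design where 8-mer combinatorics themselves
are the claim, 250-peak sets with 10 shuffles for CM recovery (20 seeds),
and 20 random truth motifs for the derivation-recovery benchmark.

## Known limitations

* The simulator's noise model is deliberately simple; success thresholds
  tuned on it say nothing about marginal real experiments.
* PWM derivation implements one of the four algorithms used by the original
  compendium; selection among externally fitted candidates is supported but
  those fitters are not reimplemented.
* The central-enrichment test is a labeled simplification, not a CentriMo
  replacement.
* Clustering equivalence with the original PWM-clustering tool is not
  claimed (its column search is unpublished).
* Homology thresholds beyond NHR/DM default to a single conservative value;
  a fuller per-class table would come from external compendia.
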