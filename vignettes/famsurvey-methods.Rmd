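---
title: "Methods: gene-family census, duplication dating and nodule expression analysis"
author: "famsurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family census, duplication dating and nodule expression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

famsurvey re-implements, as a reusable and tested pipeline, the analysis
pattern of a genome-wide survey of a plant gene family — modelled on
papain-like cysteine protease (PLCP) surveys in legumes. Five stages run
over one genome's protein/CDS FASTA, GFF3 gene models and a conserved-domain
hit table:

1. **Census** — family membership, pseudogene calling, protein
   physicochemistry (molecular weight, isoelectric point).
2. **Phylogeny** — p-distance neighbor-joining with bootstrap support and
   exemplar-based clade group assignment.
3. **Duplication** — tandem clusters, whole-genome-duplication (WGD)
   segment-pair identification with two validation criteria, NG86 Ka/Ks,
   molecular dating and selection classification.
4. **Gene structure** — exon/intron/UTR summaries and per-group statistics.
5. **Expression** — geNorm reference-gene stability, efficiency-corrected
   relative quantification of a nodule time course, temporal pattern
   classification and root-nodule-symbiosis (RNS) candidate selection.

A synthetic-genome generator with complete ground truth backs every stage's
validation, so a green test suite demonstrates recovery of a known history,
not agreement with any particular real genome.

# Models and procedures

## Pseudogene rules

A family locus is a putative pseudogene iff its peptide is shorter than 150
residues, it lacks a peptidase_C1 domain hit, or its best peptidase_C1 hit
covers less than `truncationCoverageMin` of the reference domain length.
Exactly 150 residues is a member (the rule is strictly "< 150"). The
coverage cutoff operationalises "large fragment deletion"; no published
value exists, so the default is 0.6 and the parameter is exposed in
`surveyConfig()`.

## Protein physicochemistry

Molecular weight is the sum of average isotopic residue masses plus one
water (18.01524 Da). The isoelectric point uses the Bjellqvist/ExPASy pKa
set (side chains D 4.05, E 4.45, C 9.0, Y 10.0, H 5.98, K 10.0, R 12.0;
residue-specific terminal pKa) with Henderson–Hasselbalch charges; the net
charge is monotone decreasing in pH, so bisection on [0, 14] to 1e-3 finds
the unique root. Tests compare both against independently coded brute-force
oracles (atomic-mass summation; 0.001-pH grid search).

## NG86 Ka/Ks

Synonymous (S) and nonsynonymous (N) sites are counted per codon as the
fraction of the three possible changes per position that preserve the amino
acid, averaged over both sequences; changes into stop codons count as
nonsynonymous. Differences (Sd, Nd) between codons differing at k positions
are averaged with equal weight over all k! mutational pathways, excluding
pathways that pass through a stop codon (if every pathway is blocked, all
are used). Proportions pS = Sd/S and pN = Nd/N are corrected for multiple
hits by Jukes–Cantor, d = −3/4·log(1 − 4p/3); p ≥ 0.75 is reported as a
distinct saturation error. This is deliberately the classic
equal-pathway-weight method rather than a transition/transversion- or
codon-frequency-weighted estimator (such as PAML's YN00): it is
self-contained and exhaustively checkable, and the package's dating and
selection checks consume printed Ka/Ks values as inputs, so the method
choice never touches that surface. The implementation is cross-checked
against an exhaustive pathway-enumeration oracle and against an external
reference implementation on a fixture pair.

## Dating and selection

Divergence times use T = Ks/(2λ) × 10⁻⁶ Mya with λ = 6.1 × 10⁻⁹
synonymous substitutions/site/year by default (the clock commonly applied
to the recent *Glycine* WGD), reported to two decimals. ω = Ka/Ks < 1 is
classified purifying, > 1 directional, = 1 neutral.

## Tandem clusters and segment pairs

Tandem clusters are maximal same-chromosome runs of family genes with at
most `tandemMaxIntervening` non-family genes (default 1) between
consecutive members. WGD segment-pair candidates are family gene pairs on
different chromosomes whose Ks falls in `wgdKsWindow` (default
[0.06, 0.45], bracketing the observed 0.10–0.34 recent-WGD cohort with
margin), reduced to mutual-best matches by Ks and merged into multi-gene
segments only when tandem-adjacent on both chromosomes — so multi-gene
segment pairs arise exactly where tandem arrays duplicated, as in the two
large chromosome-6/12-style pairs. Two validation criteria follow:

* **Criterion 1 (phylogeny)** — for each member pair, the smallest clade
  (bipartition side) of the family tree containing both genes must contain
  only this segment pair's family genes (tandem siblings included).
* **Criterion 2 (collinearity)** — the longest chain of homolog-pair
  anchors strictly increasing on both segments, within ±`collinearityWindow`
  genes (default 25) of the lowest-Ks focal pair and taking the better of
  forward and reversed orientation of the second segment, must reach
  `collinearityMinAnchors` (default 3: the focal pair plus two flanking
  anchors). Anchors are the family homolog pairs plus any supplied
  paralogy table (e.g. a precomputed synteny list), mirroring how flanking
  regions evidence collinearity in practice.

The representative Ks of a segment pair is the minimum member-pair Ks
(configurable to the mean); the table prints one Ks per pair and no
published reduction rule exists, and the minimum is the member pair least
affected by lineage-specific acceleration.

## Phylogeny

Distances are peptide p-distances with pairwise gap exclusion. Trees use
the standard Saitou–Nei neighbor-joining agglomeration; negative branch
lengths are clamped to zero with the deficit moved to the sibling edge so
joined distances are preserved, and Q-ties break towards the
lexicographically smallest pair of subtree labels, making output
deterministic. Bootstrap resamples alignment columns with replacement and
attaches to each internal node the fraction of replicate trees containing
its bipartition. Group assignment gives each unlabelled leaf the group of
the smallest clade containing it and at least one exemplar; when the
minimal clades tie or mix groups, the leaf is "unassigned" (the behaviour
a basal outlier sequence shows). Maximum-likelihood and Bayesian tree
inference are deliberately out of scope; NJ with bootstrap carries the
segment-pair criterion. The built-in star-progressive aligner (match 1,
mismatch −1, gap −2, merged on the longest sequence) exists for synthetic
data; real analyses should supply a pre-computed alignment.

## Expression analysis

geNorm stability: with relative quantities Q = E^(minCt − Ct) from
replicate-mean Ct values, M_j is the mean over other candidates k of the
SD across samples of log2(Q_j/Q_k); candidates are ranked ascending (the
classic screen keeps the best two of four). Relative expression divides
the target quantity by the geometric mean of the reference quantities and
anchors the first-timepoint (12 days after inoculation) sample at exactly
1; with E = 2 and one reference this is algebraically 2^−ΔΔCt. Replicate
SDs propagate to fold changes by the delta method.

Temporal classes over the five nodule timepoints (12/30/42/64/84 days)
use a consecutive-ratio significance threshold (`foldChangeThreshold`,
default 2): senescence_up (a rise, no fall, peak last), development_down
(a fall, no rise), mid_peak (interior peak at the 2nd or 3rd timepoint
with a fall after it), down_then_up (first significant move a fall, later
a rise), up_then_down (rise first, later a fall, peak at the penultimate
timepoint), bimodal (two local maxima within the threshold of the global
maximum, with both a rise and a fall), flat (no significant moves), tried
in that order. One rule was sharpened during design: an "up then down"
profile always has an interior global maximum, so a mid-peak rule defined
as *any* interior maximum would shadow it entirely; restricting mid_peak
to early-to-middle peaks (the "peaks at 30 or 42 days" phenotype) makes
both classes reachable and matches the biology the classes describe.

RNS candidates are genes strictly above the per-sample
`expressionHighQuantile` quantile (default 0.75; "highly expressed" has no
published cutoff) in at least one symbiosis-related tissue *and* at least
one nodule-stage sample. Heatmap preparation is log2(x + 1) with per-gene
centering.

# The synthetic world

`simConfig()` defaults state the world the recovery tests run in:

* Every ancestral gene (default 25; recovery tests use 50) is duplicated
  once genome-wide; chromosome i + n/2 carries the copies of chromosome i
  in the same order, so collinearity holds by construction.
  `shuffleOrder = TRUE` permutes each chromosome for negative controls.
* Expected synonymous divergence `wgdTargetKs` = 0.2 (the centre of the
  observed 0.10–0.34 cohort); nonsynonymous changes at `kaKsRatio` = 0.2
  of the synonymous rate, matching the purifying-selection regime.
* Tandem arrays of 3 and 2 genes (the chromosome-6 pattern) at
  `tandemTargetKs` = 0.03 — below the WGD Ks window, so tandem siblings
  join segment spans without becoming WGD member pairs.
* Pseudogene fraction 0.085 (9 of 106 loci), alternating the two
  mechanisms: truncation to 100 codons (< 150 residues) and an internal
  deletion removing half of the peptidase_C1 domain (coverage 0.45 < 0.6)
  while keeping the peptide above 150 residues, so each census rule has a
  clean trigger path.
* Genes are built from fourfold-degenerate codon families (ATG + GCN,
  GTN, GGN, ACN, CCN, TCN), giving each codon exactly one synonymous
  site. Synonymous evolution is a per-site Poisson Jukes–Cantor process on
  third positions of fourfold codons; nonsynonymous events hit positions
  1–2 with stop-codon rejection. "True Ks" is therefore exactly the
  quantity NG86 estimates, and the estimator is calibrated (mean over 50
  pairs within 3 SE of the target). The amino-acid alphabet is
  correspondingly reduced — a deliberate trade of compositional realism
  for an unbiased, well-defined divergence oracle.
* One family locus per 100 genes. Real genomes are sparser still (soybean
  has roughly one PLCP per 580 annotated genes); at this density, chance
  anchor chains in a ±25-gene window are rare enough that a shuffled
  genome fails the collinearity criterion, which is the property the
  negative control tests. Every 12th background gene pair appears in the
  emitted paralogy table as a detectable WGD duplicate, giving about five
  anchors per window on the true layout.
* qPCR: Ct = baseline − log_E(relative quantity) + N(0, `qpcrNoiseSd`),
  three replicates, E = 2 by default; two designed flat references (REF1,
  REF2) and two drifting ones (REF3 up, REF4 down, ±3.2 log2 across the
  course) mirror the published four-candidate screen. Class mean profiles
  keep ≥ 1.3 log2 defining steps and < 1 log2 non-steps, so with 0.2
  cycles of noise the per-sample log2 error (≈ 0.14) leaves multi-sigma
  margins; ≥ 90% class recovery at 50 genes per class follows from that
  design rather than from tuning.
* The tissue matrix gives RNS-designated genes (30% of members) a 10–100×
  boost in both tissue classes, with each boosted gene designated one
  sample where its boost is maximal — so every designed candidate tops the
  upper-quartile threshold somewhere in each class, and recovery of the
  exact designed set is structural. Symbiosis-only and nodule-only decoys
  (10% each) exercise the both-classes requirement. Nodule-stage columns
  of this matrix are not additionally modulated by the temporal profiles;
  time-course structure lives in the qPCR table.

What a green suite does **not** establish: agreement with any real
genome's locus counts (106/97, 77 genes in 19 pairs, nine groups' sizes),
which depend on external database versions and are out of scope;
robustness to alignment error (synthetic proteins are equal-length);
realistic intron lengths or indel evolution; or YN00-grade Ka/Ks under
strong transition/transversion bias.

# Numerical choices and degenerate inputs

* NG86 raises distinct errors for length not divisible by 3, internal
  stop codons, gapped input, and saturated (p ≥ 0.75) proportions; a
  single trailing stop codon is trimmed.
* Dating rounds to 2 decimals at the function level, matching the
  printed-table convention the checks compare against.
* NJ accepts only symmetric finite matrices with ≥ 3 labelled taxa;
  branch lengths are written with 12 significant digits, so additive
  path-length recovery is exact to ~1e-9.
* Bisection tolerance for pI is 1e-3 pH; tests compare at 0.01.
* Bootstrap and every other stochastic operation draw from a seed carried
  in the configuration; identical configurations give byte-identical
  pipeline outputs, which the suite asserts file-by-file.
* `geNorm` M is invariant to adding a constant to all Ct values of one
  sample (quantity ratios are unchanged); the suite asserts this exactly.

# Known limitations

The NG86 estimator ignores transition/transversion and codon-usage bias
and will differ from YN00 on real data (typically modestly for Ks at the
divergences relevant here). The built-in aligner is not a general MSA
tool. Segment-pair identification assumes per-gene Ks is computable for
candidate member pairs (equal-length, in-frame CDS after filtering);
real-data use should supply Ks from a dedicated pipeline where sequences
require codon-aware alignment. Group letters on synthetic data are
arbitrary; only co-membership is meaningful.
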