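---
title: "Models and methods behind mircluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mircluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircluster)
library(dplyr)
```

`mircluster` implements a complete desk-scale pipeline for studying the
evolution of a clustered miRNA family across species: expression-based
validation of hairpins, parsimony dating of member gain and loss, seed
innovation analysis, seed-match target prediction, cross-species target
divergence, and repression testing in overexpression transcriptomes. This
vignette explains the models, the tunable parameters and the numerical
choices, and states what the synthetic-data generators do and do not
emulate.

## Expression-based validation

A candidate hairpin is accepted as a miRNA when its small-RNA read profile
meets five criteria simultaneously: at least one miR\* read; at least 20
reads on miR and miR\* combined; at least 13 base pairs between miR and
miR\* in the hairpin duplex; the three most abundant isomiRs carrying at
least 85% of the miR-arm reads; and a duplex-to-background read ratio
above 1. These thresholds are exposed as arguments of `validate_mirna()`
with the values above as defaults.

Three conventions the criteria leave open are fixed as follows.

* **Read-to-window assignment.** A read counts toward a window (miR or
  miR\*) when it overlaps it by at least half the read length
  (`min_overlap = 0.5`). Strict containment would misclassify isomiRs
  whose ends wander a few nucleotides past the window.
* **isomiR identity.** An isomiR is a unique `(start, length)` pair on
  the miR arm; ties in the top-3 ranking break by count (descending),
  then start, then length. The 85% comparison is non-strict (a fraction
  of exactly 0.85 passes).
* **Zero background.** With no background reads the ratio is reported as
  `Inf` and criterion 5 passes.

### Hairpin folding

The duplex pair count needs a secondary structure. `fold_hairpin()`
maximizes the number of base pairs (Watson–Crick plus G·U wobble) with a
minimum loop of 3 nt by dynamic programming. Base-pair maximization is
deterministic, dependency-free and adequate for counting duplex pairs; it
is *not* a thermodynamic model, and when several structures attain the
maximum the traceback returns one of them (preferring the outermost
admissible partner). Because an equal-count structure can contain a few
stray long-range pairs, `locate_star()` trims partner positions further
than one mature length from the partner median before forming the miR\*
interval, then applies the canonical 2-nt 3' overhang shift. A structure
from any external folding tool can be supplied as a dot-bracket string via
`fold_from_dotbracket()`, which validates balance and complementarity.

## Dating gain and loss

Member origination follows Dollo parsimony: a miRNA arises once, at the
most recent common ancestor of the species with *verified expression*, and
may be lost any number of times. Sequence homologs without validated
expression count as absent. `infer_losses()` returns the minimal loss set:
the stems of the maximal subtrees below the origin whose scored leaves are
all absent. Species absent from the presence matrix are treated as
unscored and never force or block a loss.

`classify_age()` labels a member *new* when its origin lies within the
subtree rooted at the ingroup-side child of a user-chosen reference split
(the child itself included — a member originating exactly on the ingroup
stem belongs to the post-split class); everything else, including origins
at the split itself, is *old*. `subcluster()` chains loci on one
chromosome into sub-clusters by single-linkage with a default maximum
inter-locus gap of 1000 nt, reporting singletons as orphans; overlapping
loci are chained with a warning.

## Seed innovation

The dominant mature product of a hairpin in a species is the
highest-count isomiR (`dominant_mature()`); expression-weighted
alternatives are deliberately out of scope. Arms are assigned relative to
the loop enclosed by the innermost base pair; a count tie between arms is
an error demanding manual curation rather than a silent coin flip. The
seed is positions 2–8 of the mature sequence.

`classify_change()` compares one member between two species: different
arms mean *arm switching*; on the same arm, a seed reproducible as a
shifted register (at most 5 nt) of the partner's mature sequence means
*seed shifting*; otherwise the difference is a *substitution* (with a
warning when the register also moved beyond the window — 5 nt separates
plausible Drosha/Dicer processing shifts from unrelated products).

`place_events()` maps the composite state (arm, seed) on the tree
restricted to the species bearing the member and enumerates *all*
minimum-change ancestral labelings (feasible because the trees in this
setting have few species). Each state change becomes an event; when the
optimal labelings disagree on the branch, the event lists every candidate
branch and is flagged unresolved — the honest answer for changes adjacent
to the root, where parsimony cannot orient the event. The enumeration's
change count is cross-checked against an independent Fitch implementation
in the test suite.

## Target prediction

Counts are TPM-normalized (`compute_tpm()`), and genes with across-sample
mean TPM below 1 are removed before scanning (`filter_expressed()`; the
boundary value is kept). `find_sites()` scans the UTR sense strand for
the reverse complement of the seed: a full 7-nt match followed by A is an
**8mer**, without the A a **7mer-m8**, and a match to mature 2–7 followed
by A a **7mer-1A**. The default site classes are `{8mer, 7mer-m8}` — the
two strongest canonical classes; 7mer-1A can be enabled by argument. Each
position reports its most specific class unless `collapse = FALSE`.
No conservation or context scoring is applied: site presence alone
defines a target, matching the analysis this package supports.

## Cross-species divergence

Sets are compared through a one-to-one ortholog map supplied as data (how
cross-species gene identity was established is upstream of this package);
genes without a tuple stay in species-specific counts and in the union
but can never be shared. The headline percentage is shared/union
(Jaccard × 100): with sets of 36 and 35 sharing 6, this gives
6/65 = 9.2%. Because the denominator behind alternative conventions is
often unstated in published figures, per-species percentages
(shared/set-size) are emitted alongside. `pooled_overlap()` compares the
within-species unions over members and attributes every shared ortholog
tuple to the members targeting it in each species, which makes target
handover between members directly visible.

## Repression analysis

Replicates are averaged before fold changes (`log2_fold_changes()`);
genes with zero mean in either condition are excluded and listed. The
target-vs-background comparison is a two-sided two-sample
Kolmogorov–Smirnov test: D is the sup-distance between the empirical
CDFs, and the p-value comes from the asymptotic Kolmogorov series with
effective sample size $n_x n_y/(n_x+n_y)$, or — when either sample has
fewer than 10 values — from permutation of the group labels, with full
enumeration whenever at most 50,000 assignments exist. The direction of
a shift is read off the median difference, not the test. The background
is "expressed genes that are not predicted targets of the focal miRNA";
a full-transcriptome background can be passed explicitly instead.
Down-regulated genes are called at `lfc <= -log2(1.2)` by default.

`position9_composition()` tabulates the UTR base pairing mature position
9 — the position immediately adjacent to the m8 end of a site (site start
− 1 for 8mer/7mer-m8 sites in 0-based coordinates; − 2 for 7mer-1A) —
and `compare_position9()` tests a base's enrichment between two species
with Fisher's exact test (two-sided, hypergeometric).

## The synthetic-data generators

The generators produce inputs with the statistical structure the analysis
assumes, so every stage can be tested end to end against known truth.

* **Cluster histories.** `simulate_cluster_history()` places each member
  at an origin node and knocks it out below sampled loss branches. The
  random sampler constrains losses to be pairwise non-nested, to never
  silence an entire child subtree of the origin, and to never complete an
  all-absent sibling pair — exactly the regime in which Dollo dating can
  recover the truth, which is what the recovery tests assert. Histories
  violating those constraints (e.g. a loss wiping out one whole side of
  the origin) are biologically possible but not identifiable by any
  parsimony method; the package would then return the shallower MRCA.
* **Read profiles.** Total depth is negative-binomial (mean 200, size 10
  by default); reads split into background (default fraction 0.05; 0 in
  noiseless tests), miR and miR\* at a 10:1 miR:miR\* ratio; miR-arm
  reads spread over (start, length) offsets within ±3 nt of the canonical
  product by a Dirichlet-multinomial with weight 100 on the canonical
  offset and 0.1 on each alternative — a clean-library regime whose top-3
  isomiR fraction sits well above the 85% threshold. miR\* reads sit at
  the duplex partner position with the 2-nt 3' overhang; background reads
  are placed where they overlap neither window by ≥ 50%.
* **UTR sets.** Background composition is 60% AU (fly-like 3'UTRs),
  lengths uniform on 150–300 nt by default. Non-target genes are
  rejection-sampled to contain no qualifying site of *any* class for
  *any* member's seed — screening all members prevents accidental
  cross-member targets from corrupting pooled-overlap truth. Target genes
  receive at least one exact planted site for their member and are
  re-screened against the other members. A rejection cap (200 attempts)
  turns pathological configurations into an instructive error.
* **Expression.** Gene baselines are lognormal (meanlog log 100, sdlog
  1); every observation gets multiplicative lognormal noise (sd 0.25 on
  the natural-log scale by default); true targets are divided by the
  repression factor *f* in the treatment, so their expected log2 fold
  change is $-\log_2 f$. The default *f* = 1.3 reflects the weak
  repression regime typical of miRNA overexpression; *f* = 1 is the null.

What the generators do **not** emulate: sequence evolution of precursors
(seed events are imposed by schedule, not evolved), mapping ambiguity and
multi-locus cross-mapping of reads, UTR secondary structure and site
accessibility, count overdispersion structure beyond a single NB draw per
library, and any correlation between genes. Passing tests therefore
demonstrate correctness of the inference logic under the stated model,
not robustness to every artifact of real libraries.

## Problem sizes and determinism

The test and acceptance runs use desk-scale sizes chosen to make the
statistical checks sharp but quick: 200 seeded replicates for the
validation pass-rate and for each KS operating-characteristic run (100
targets vs 2000 non-targets, two replicates per condition), 100 seeded
cluster histories and event schedules, 1000 random (UTR, seed) pairs for
the site-scanner oracle, and exhaustive enumeration oracles for KS
(samples of ≤ 6), Fisher (margins ≤ 30) and folding (sequences ≤ 13 nt).
Every stochastic function takes an explicit seed and is byte-reproducible
given it; `scripts/acceptance.R` derives all of its seeds from the single
`--seed` argument.

## Known limitations

* Base-pair maximization can report slightly different (equal-count)
  structures for the same sequence across traceback conventions; only
  pair counts and the trimmed miR\* interval are contract-stable.
* Ancestral-state enumeration in `place_events()` is exponential in the
  number of internal nodes and intended for the few-species setting it
  serves (≲ 10 species with the member).
* The ortholog map is trusted as given; paralogy is handled only by
  excluding non-one-to-one tuples upstream.
* KS p-values with heavily tied data inherit the usual conservativeness
  of the asymptotic distribution; the permutation path is exact but only
  engaged for small samples unless requested.
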