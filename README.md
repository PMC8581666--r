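# mircluster

Evolutionary analysis of clustered microRNAs from small-RNA read profiles,
species phylogenies, 3'UTR sequences and expression matrices.

Young miRNA clusters gain and lose members rapidly. Individual members can
swap the arm of the precursor that yields the dominant mature product
(*arm switching*) or move the Drosha/Dicer processing register on the same
arm (*seed shifting*); either event replaces the seed — nucleotides 2–8 of
the mature sequence — and with it essentially the whole target repertoire,
while the pooled target set of the cluster can stay comparatively stable
because a 3'UTR dropped by one member may be picked up by another.
`mircluster` packages every step of this analysis for cross-species studies
of such clusters (the motivating system is an X-linked, testis-expressed
12-member cluster in *Drosophila*):

* **Validation** — five expression criteria applied to per-hairpin read
  profiles: (1) ≥ 1 miR\* read, (2) ≥ 20 reads on miR + miR\*, (3) ≥ 13
  base pairs in the miR:miR\* duplex, (4) top-3 isomiRs ≥ 85% of miR-arm
  reads, (5) duplex:background read ratio > 1. The duplex comes from a
  base-pair-maximization fold (Watson–Crick + G·U, minimum loop 3) or an
  externally supplied dot-bracket.
* **Dating** — Dollo parsimony: a member originates at the MRCA of the
  species with verified expression; losses are the minimal branch set
  (maximal all-absent subtrees); members are classified *new*/*old*
  relative to a reference split of the tree. Genomic sub-clusters are
  chained by an inter-locus gap threshold.
* **Seed innovation** — dominant mature products from read profiles, seed
  extraction, classification of inter-species differences (arm switch,
  seed shift, substitution) and Fitch-parsimony placement of events on
  branches, reporting every candidate branch when parsimony cannot decide.
* **Targets** — TPM normalization, the mean-TPM ≥ 1 expression filter, and
  canonical seed-match scanning (8mer, 7mer-m8, optionally 7mer-1A) of
  3'UTRs; per-member and pooled target sets.
* **Divergence** — cross-species overlap through one-to-one ortholog
  tuples, with the shared/union percentage convention and per-species
  denominators, plus member attribution for pooled shared targets.
* **Repression** — log2 fold changes between control and overexpression
  transcriptomes, two-sample Kolmogorov–Smirnov comparison of targets vs
  background (asymptotic, or permutation for small samples), the 1.2-fold
  down-regulation cutoff, and the Fisher-exact comparison of the base
  composition opposite mature position 9 at target sites.
* **Synthetic data** — generators for cluster histories on a tree, hairpin
  read profiles (negative-binomial depth, Dirichlet-multinomial isomiRs,
  miR\* at the duplex position with the 2-nt 3' overhang, background),
  3'UTR sets with planted sites and clean backgrounds, and paired
  control/treatment expression with weak multiplicative repression.

Everything takes and returns tibbles, chains with the pipe, and exposes
`tidy()`/`glance()` methods plus `autoplot()`/`plot_*()` displays.

## Worked example

```r
library(mircluster)
library(dplyr)

# 1. validate a hairpin from its small-RNA read profile
hp     <- make_hairpin("UAUUGCACUUGAGACGGCCUGA")
prof   <- simulate_read_profile(hp, hairpin_id = "mir-sim", seed = 42)
fold   <- fold_hairpin(hp$seq, id = "mir-sim")
report <- validate_mirna(prof[-1], fold)
report
#> <mirna_validation> mir-sim: PASS
#>   criteria: c1 T c2 T c3 T c4 T c5 T
glance(report)[, c("star_reads", "duplex_reads", "duplex_pairs", "verdict")]
#>   star_reads duplex_reads duplex_pairs verdict
#> 1         31          265           19 TRUE
```

31 miR\* reads, 265 duplex reads and 19 duplex base pairs clear the
thresholds of 1, 20 and 13, so the hairpin is validated.

```r
# 2. date member origination on the species tree
tr <- read_newick("(((mel:5,sim:5):20,pse:25):35,vir:60);")
presence <- tibble(
  member  = rep(c("mir-975", "mir-972", "mir-979"), each = 4),
  species = rep(c("mel", "sim", "pse", "vir"), 3),
  present = c(TRUE, TRUE, FALSE, TRUE,
              TRUE, TRUE, FALSE, FALSE,
              TRUE, FALSE, FALSE, FALSE))
date_origins(presence, tr, ingroup_tip = "mel") %>%
  select(member, origin_label, n_losses, age_class)
#>   member  origin_label    n_losses age_class
#> 1 mir-975 mel|pse|sim|vir        1 old
#> 2 mir-972 mel|sim                0 new
#> 3 mir-979 mel                    0 new
```

A member expressed in all three distant species dates to the root (*old*)
with one inferred loss where expression is absent; members confined to the
ingroup date to shallower nodes and are *new*.

```r
# 3. cross-species overlap of down-regulated target sets
genes <- paste0("g", 1:200)
map   <- tibble(tuple = paste0("og", 1:200), mel = genes, sim = genes)
shared_downregulated(list(mel = paste0("g", 1:36),
                          sim = paste0("g", 31:65)), map) %>%
  select(shared, union, pct_union)
#>   shared union pct_union
#> 1      6    65      9.23
```

Two sets of 36 and 35 down-regulated targets sharing 6 orthologs overlap
by 6/65 = 9.2% under the shared-over-union convention.

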