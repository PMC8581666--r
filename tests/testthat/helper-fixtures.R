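# Shared fixtures: the four-species study tree, the cluster's presence
# matrix as reported per species, the genomic locus layout, and small
# builders used across test files.

study_tree <- function() {
  read_newick("(((mel:5,sim:5):20,pse:25):35,vir:60);")
}

# expression-verified presence of the twelve cluster members in the four
# species with testis small-RNA libraries (the two mir-4966 copies are
# separate loci)
study_presence <- function() {
  members_old <- c("mir-973", "mir-974", "mir-975", "mir-976", "mir-977", "mir-978")
  members_ms <- c("mir-972", "mir-9369", "mir-2499", "mir-4966-1", "mir-4966-2")
  species <- c("mel", "sim", "pse", "vir")
  rows <- list()
  for (m in members_old) {
    rows[[m]] <- tibble::tibble(member = m, species = species,
                                present = species %in% c("mel", "sim", "vir"))
  }
  for (m in members_ms) {
    rows[[m]] <- tibble::tibble(member = m, species = species,
                                present = species %in% c("mel", "sim"))
  }
  rows[["mir-979"]] <- tibble::tibble(member = "mir-979", species = species,
                                      present = species == "mel")
  dplyr::bind_rows(rows)
}

# locus coordinates consistent with three sub-clusters each spanning
# under 1 kb, plus the orphan between the first two
study_loci <- function() {
  tibble::tribble(
    ~member,       ~start, ~end,
    "mir-972",          0,    80,
    "mir-9369",       180,   260,
    "mir-973",        400,   480,
    "mir-974",        600,   680,
    "mir-2499",      2500,  2580,
    "mir-4966-1",    4500,  4580,
    "mir-4966-2",    4700,  4780,
    "mir-975",       4900,  4980,
    "mir-976",       5100,  5180,
    "mir-977",       5300,  5380,
    "mir-978",       7000,  7080,
    "mir-979",       7200,  7280
  )
}

# an identity ortholog map over a gene universe
identity_map <- function(genes, species) {
  map <- tibble::tibble(tuple = paste0("og", seq_along(genes)))
  for (sp in species) map[[sp]] <- genes
  map
}

random_seed7 <- function() {
  paste(sample(c("A", "C", "G", "U"), 7, replace = TRUE), collapse = "")
}

# independent maximum-pairing oracle: exhaustive recursion over all nested
# structures (no memoisation; valid only for short sequences)
brute_max_pairs <- function(seq) {
  b <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  can <- function(x, y) paste(x, y) %in% c("A U", "U A", "C G", "G C", "G U", "U G")
  rec <- function(i, j) {
    if (j - i < 4) return(0L)
    best <- rec(i + 1L, j)
    for (k in (i + 4L):j) {
      if (can(b[i], b[k])) {
        inner <- if (k - i >= 5L) rec(i + 1L, k - 1L) else 0L
        rest <- if (k < j) rec(k + 1L, j) else 0L
        best <- max(best, 1L + inner + rest)
      }
    }
    best
  }
  if (length(b) < 5) return(0L)
  rec(1L, length(b))
}

# independent site-scanning oracle built on Biostrings pattern matching
oracle_sites <- function(utr, seed, site_classes = c("8mer", "7mer-m8")) {
  to_dna <- function(x) Biostrings::DNAString(chartr("U", "T", x))
  m <- mircluster::rna_revcomp(seed)
  m6 <- substr(m, 2, 7)
  subject <- to_dna(utr)
  hits7 <- Biostrings::start(Biostrings::matchPattern(to_dna(m), subject))
  hits8 <- Biostrings::start(Biostrings::matchPattern(to_dna(paste0(m, "A")), subject))
  hits6a <- Biostrings::start(Biostrings::matchPattern(to_dna(paste0(m6, "A")), subject))
  out <- tibble::tibble(utr_position = integer(), site_class = character())
  if (length(hits7)) {
    cls <- ifelse(hits7 %in% hits8, "8mer", "7mer-m8")
    out <- dplyr::bind_rows(out, tibble::tibble(utr_position = hits7 - 1L,
                                                site_class = cls))
  }
  if (length(hits6a)) {
    part_of_8 <- hits6a %in% (hits8 + 1L)
    keep <- hits6a[!part_of_8]
    if (length(keep)) {
      out <- dplyr::bind_rows(out, tibble::tibble(utr_position = keep - 1L,
                                                  site_class = "7mer-1A"))
    }
  }
  out <- out[out$site_class %in% site_classes, ]
  out[order(out$utr_position), ]
}

# exact two-sample KS permutation p-value by full enumeration of label
# assignments (test-side oracle, independent of the package path)
enumerate_ks_p <- function(x, y) {
  pool <- c(x, y)
  nx <- length(x)
  d_of <- function(a, b) {
    pts <- sort(unique(c(a, b)))
    max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), 0)))
  }
  d0 <- d_of(x, y)
  idx <- utils::combn(length(pool), nx)
  ds <- apply(idx, 2, function(i) d_of(pool[i], pool[-i]))
  mean(ds >= d0 - 1e-12)
}

# exact two-sided Fisher p by hypergeometric enumeration over all tables
# with the observed margins
enumerate_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(a_vals, function(a) {
    choose(c1, a) * choose(n - c1, r1 - a) / choose(n, r1)
  }, 0)
  p_obs <- probs[a_vals == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
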