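# Synthetic-data generators emulating the study conditions: a miRNA
# cluster evolving on a species tree with a single origination and
# independent losses, per-species hairpin read profiles with dominant
# products, isomiR spread, miR* reads and background, 3'UTR sets with
# planted seed-match sites, and paired control/overexpression expression
# matrices with weak multiplicative repression on true targets.

#' Default species tree for simulations
#'
#' Four species, two on the ingroup side of the root split and one deep
#' outgroup lineage, mirroring a melanogaster-group pair plus an obscura
#' group and a distant subgenus.
#'
#' @return A rooted `phylo` tree with tips `mel`, `sim`, `pse`, `vir`.
#' @export
sim_tree <- function() {
  read_newick("(((mel:5,sim:5):20,pse:25):35,vir:60);")
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

#' Sample a random cluster history on a tree
#'
#' Draws an origin node and a set of loss branches for each member, under
#' the constraints that make the history exactly recoverable by Dollo
#' parsimony: losses are pairwise non-nested, never silence an entire
#' child subtree of the origin, and never complete an all-absent sibling
#' pair.
#'
#' @param tree A rooted `phylo` tree.
#' @param n_members Number of members to draw.
#' @param p_loss Per-candidate-branch probability of attempting a loss.
#' @param seed Optional RNG seed (the draw is deterministic given it).
#' @return Tibble `member`, `origin` (node number), `losses` (list of
#'   child-node numbers).
#' @export
sim_cluster_config <- function(tree, n_members = 4, p_loss = 0.3, seed = NULL) {
  with_seed_if(seed, {
    n_tip <- ape::Ntip(tree)
    internal <- n_tip + seq_len(tree$Nnode)
    purrr::map_dfr(seq_len(n_members), function(i) {
      origin <- sample(c(internal, seq_len(n_tip)), 1)
      losses <- integer(0)
      if (origin > n_tip) {
        present <- descendant_tips(tree, origin)
        cand <- descendant_nodes(tree, origin)
        cand <- cand[sample.int(length(cand))]
        for (v in cand) {
          if (runif(1) > p_loss) next
          v_tips <- descendant_tips(tree, v)
          new_present <- setdiff(present, v_tips)
          if (length(new_present) == 0) next
          # keep the MRCA of survivors at the origin
          if (infer_origin(tree, new_present) != origin) next
          # non-nested with existing losses
          nested <- any(vapply(losses, function(u) {
            v %in% descendant_nodes(tree, u) || u %in% descendant_nodes(tree, v)
          }, TRUE))
          if (nested) next
          # sibling subtree must retain a bearer (no mergeable loss pair)
          parent <- tree$edge[tree$edge[, 2] == v, 1]
          sibs <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], v)
          sib_tips <- unlist(lapply(sibs, function(s) descendant_tips(tree, s)))
          if (!any(sib_tips %in% new_present)) next
          losses <- c(losses, v)
          present <- new_present
        }
      }
      tibble(member = sprintf("m%02d", i), origin = as.integer(origin),
             losses = list(as.integer(losses)))
    })
  })
}

#' Simulate a cluster presence/absence history
#'
#' Each member is present in exactly the leaves descending from its origin
#' node and not below any loss branch.  A loss branch outside the origin's
#' subtree is a hard error.
#'
#' @param tree A rooted `phylo` tree.
#' @param members Tibble `member`, `origin`, `losses` (as from
#'   [sim_cluster_config()]); if `NULL`, one is drawn.
#' @param n_members,p_loss,seed Passed to [sim_cluster_config()] when
#'   `members` is `NULL`.
#' @return A list with `presence` (long tibble `member`, `species`,
#'   `present`) and `truth` (the member configuration).
#' @export
simulate_cluster_history <- function(tree, members = NULL, n_members = 4,
                                     p_loss = 0.3, seed = NULL) {
  if (is.null(members)) {
    members <- sim_cluster_config(tree, n_members, p_loss, seed)
  }
  n_tip <- ape::Ntip(tree)
  presence <- purrr::map_dfr(seq_len(nrow(members)), function(i) {
    origin <- resolve_node(tree, members$origin[[i]])
    losses <- vapply(members$losses[[i]], function(v) resolve_node(tree, v), 0L)
    under <- if (origin <= n_tip) origin else c(origin, descendant_nodes(tree, origin))
    if (length(losses) && !all(losses %in% setdiff(under, origin))) {
      abort(paste0("loss branch not under origin for member ", members$member[i]))
    }
    present_tips <- descendant_tips(tree, origin)
    for (v in losses) present_tips <- setdiff(present_tips, descendant_tips(tree, v))
    tibble(member = members$member[i], species = tree$tip.label,
           present = tree$tip.label %in% present_tips)
  })
  list(presence = presence, truth = members)
}

#' Build a synthetic hairpin around a mature sequence
#'
#' The precursor is a perfect inverted repeat of the mature sequence
#' around a short loop, with non-pairing flanks, so the duplex structure
#' and the miR* position are known by construction.
#'
#' @param mature Mature sequence (RNA; 18-26 nt).
#' @param arm Which arm carries the mature product (`"5p"` or `"3p"`).
#' @param flank5,flank3 Flanking sequences (complementary by default, so
#'   the lower stem extends below the duplex as in real pri-miRNAs).
#' @param loop Loop sequence (>= 3 nt).
#' @return A list: `seq`, `mir_start` (0-based), `mir_len`, `arm`,
#'   `star_start`, `star_len` (the canonical miR* with 2-nt 3' overhang).
#' @export
make_hairpin <- function(mature, arm = c("5p", "3p"),
                         flank5 = "CACACACACACACAC",
                         flank3 = "GUGUGUGUGUGUGUG",
                         loop = "AAACAAACAAAC") {
  arm <- match.arg(arm)
  mature <- normalize_rna(mature)
  if (nchar(mature) < 18 || nchar(mature) > 26) abort("mature must be 18-26 nt")
  m <- nchar(mature)
  star <- rna_revcomp(mature)
  if (arm == "5p") {
    seq <- paste0(flank5, mature, loop, star, flank3)
    mir_start <- nchar(flank5)
    star_start <- nchar(flank5) + m + nchar(loop) + 2L
  } else {
    seq <- paste0(flank5, star, loop, mature, flank3)
    mir_start <- nchar(flank5) + m + nchar(loop)
    star_start <- nchar(flank5) - 2L
  }
  list(seq = seq, mir_start = mir_start, mir_len = m, arm = arm,
       star_start = star_start, star_len = m)
}

#' Simulate a small-RNA read profile for a hairpin
#'
#' Total depth is negative-binomial; reads split into background, miR-arm
#' and miR*-arm components (miR:miR* at `star_ratio`); miR-arm reads
#' spread over isomiRs by a Dirichlet-multinomial on (start, length)
#' offsets within ±3 nt of the canonical product; miR* reads sit at the
#' duplex partner position with the canonical 2-nt 3' overhang; background
#' reads fall outside both windows.
#'
#' @param hairpin A list from [make_hairpin()] (or with elements `seq`,
#'   `mir_start`, `mir_len`).
#' @param depth_mean,depth_size Negative-binomial mean and size of total
#'   depth.
#' @param star_ratio Expected miR : miR* count ratio.
#' @param isomir_alpha Dirichlet weight on the canonical (0,0) offset.
#' @param isomir_alpha_off Dirichlet weight on each off-canonical offset.
#' @param background_frac Expected fraction of background reads.
#' @param hairpin_id Id written into the profile.
#' @param seed Optional RNG seed.
#' @return A read-profile tibble `hairpin_id`, `start`, `length`, `count`
#'   (empty at depth 0).
#' @export
simulate_read_profile <- function(hairpin, depth_mean = 200, depth_size = 10,
                                  star_ratio = 10, isomir_alpha = 100,
                                  isomir_alpha_off = 0.1,
                                  background_frac = 0.05,
                                  hairpin_id = "hp", seed = NULL) {
  stopifnot(nchar(hairpin$seq) >= hairpin$mir_len + 20)
  with_seed_if(seed, {
    L <- nchar(hairpin$seq)
    star <- if (!is.null(hairpin$star_start)) {
      list(start = hairpin$star_start,
           end = hairpin$star_start + hairpin$star_len)
    } else {
      locate_star(fold_hairpin(hairpin$seq, id = hairpin_id),
                  hairpin$mir_start, hairpin$mir_len)
    }
    empty <- tibble(hairpin_id = character(), start = integer(),
                    length = integer(), count = integer())
    n_total <- rnbinom(1, size = depth_size, mu = depth_mean)
    if (n_total == 0) return(empty)
    n_bg <- rbinom(1, n_total, background_frac)
    n_dup <- n_total - n_bg
    n_star <- rbinom(1, n_dup, 1 / (1 + star_ratio))
    n_mir <- n_dup - n_star

    rows <- list()
    if (n_mir > 0) {
      offs <- expand.grid(ds = -3:3, dl = -3:3)
      alpha <- ifelse(offs$ds == 0 & offs$dl == 0, isomir_alpha, isomir_alpha_off)
      w <- rgamma(nrow(offs), shape = alpha)
      p <- w / sum(w)
      cnt <- as.integer(rmultinom(1, n_mir, p))
      keep <- cnt > 0
      starts <- hairpin$mir_start + offs$ds[keep]
      lens <- hairpin$mir_len + offs$dl[keep]
      ok <- starts >= 0 & starts + lens <= L & lens >= 18
      rows$mir <- tibble(start = as.integer(starts[ok]),
                         length = as.integer(lens[ok]),
                         count = cnt[keep][ok])
    }
    if (n_star > 0) {
      rows$star <- tibble(start = star$start,
                          length = star$end - star$start,
                          count = n_star)
    }
    if (n_bg > 0) {
      bg_len <- 20L
      mirw <- list(start = hairpin$mir_start, end = hairpin$mir_start + hairpin$mir_len)
      cand <- 0:(L - bg_len)
      ov1 <- read_window_overlap(cand, bg_len, mirw)
      ov2 <- read_window_overlap(cand, bg_len, star)
      cand <- cand[ov1 < 0.5 & ov2 < 0.5]
      if (!length(cand)) abort("no room for background reads on this precursor")
      starts <- sample(cand, n_bg, replace = TRUE)
      rows$bg <- tibble(start = as.integer(starts), length = bg_len, count = 1L)
    }
    prof <- bind_rows(rows)
    if (nrow(prof) == 0) return(empty)
    prof %>%
      group_by(.data$start, .data$length) %>%
      summarise(count = sum(.data$count), .groups = "drop") %>%
      mutate(hairpin_id = hairpin_id, .before = 1) %>%
      arrange(.data$start, .data$length)
  })
}

random_rna <- function(n_len, au = 0.6) {
  paste(sample(c("A", "U", "C", "G"), n_len, replace = TRUE,
               prob = c(au / 2, au / 2, (1 - au) / 2, (1 - au) / 2)),
        collapse = "")
}

has_any_site <- function(seq, seeds) {
  for (sd in seeds) {
    if (nrow(find_sites(seq, sd, c("8mer", "7mer-m8", "7mer-1A"))) > 0) return(TRUE)
  }
  FALSE
}

#' Simulate 3'UTR sets with planted target sites
#'
#' For each species, non-target UTRs are rejection-sampled to contain no
#' qualifying site (any of the three canonical classes) for any member's
#' seed; target UTRs carry at least one exact planted site of the
#' requested class for their member's seed.  Gene ids are shared across
#' species and the ortholog map is one-to-one.
#'
#' @param seeds Tibble `species`, `member`, `seed` (the per-species seed
#'   of each member).
#' @param n_genes Genes per species.
#' @param targets Optional tibble `species`, `member`, `gene` fixing the
#'   planted targets; if `NULL`, `n_targets` genes per member per species
#'   are drawn (disjoint between members within a species).
#' @param n_targets Planted targets per member per species.
#' @param site_class Planted site class (`"8mer"` or `"7mer-m8"`).
#' @param utr_len Range of UTR lengths (nt), sampled uniformly.
#' @param au AU fraction of the background composition.
#' @param max_attempts Rejection-sampling cap per gene.
#' @param seed Optional RNG seed.
#' @return A list: `utrs` (tibble `species`, `gene`, `seq`),
#'   `ortholog_map` (tibble `tuple` + one column per species),
#'   `truth_targets` (tibble `species`, `member`, `gene`).
#' @export
simulate_utrs <- function(seeds, n_genes = 60, targets = NULL, n_targets = 8,
                          site_class = "8mer", utr_len = c(150, 300),
                          au = 0.6, max_attempts = 200, seed = NULL) {
  stopifnot(all(c("species", "member", "seed") %in% names(seeds)))
  with_seed_if(seed, {
    species <- unique(seeds$species)
    genes <- sprintf("g%04d", seq_len(n_genes))
    if (is.null(targets)) {
      targets <- purrr::map_dfr(species, function(sp) {
        mem <- seeds$member[seeds$species == sp]
        if (n_targets * length(mem) > n_genes) abort("planted site counts exceed n_genes")
        pick <- sample(genes, n_targets * length(mem))
        tibble(species = sp,
               member = rep(mem, each = n_targets),
               gene = pick)
      })
    }
    utrs <- purrr::map_dfr(species, function(sp) {
      sp_seeds <- seeds$seed[seeds$species == sp]
      sp_targets <- targets[targets$species == sp, ]
      seq_for_gene <- function(g) {
        m <- sp_targets$member[sp_targets$gene == g]
        for (attempt in seq_len(max_attempts)) {
          len <- sample(utr_len[1]:utr_len[2], 1)
          s <- random_rna(len, au)
          if (has_any_site(s, sp_seeds)) next
          if (!length(m)) return(s)
          # plant one site per targeting member, then re-screen
          for (mm in m) {
            sd <- seeds$seed[seeds$species == sp & seeds$member == mm]
            site <- if (site_class == "8mer") paste0(rna_revcomp(sd), "A") else rna_revcomp(sd)
            pos <- sample(seq_len(nchar(s) - nchar(site) - 1), 1)
            s <- paste0(substr(s, 1, pos), site,
                        substr(s, pos + nchar(site) + 1, nchar(s)))
          }
          other <- seeds$seed[seeds$species == sp & !seeds$member %in% m]
          if (length(other) && has_any_site(s, other)) next
          ok <- all(vapply(m, function(mm) {
            sd <- seeds$seed[seeds$species == sp & seeds$member == mm]
            nrow(find_sites(s, sd, site_class)) >= 1
          }, TRUE))
          if (ok) return(s)
        }
        abort("rejection sampling cap reached; use longer UTRs or fewer members")
      }
      tibble(species = sp, gene = genes,
             seq = vapply(genes, seq_for_gene, ""))
    })
    map <- tibble(tuple = paste0("og", seq_len(n_genes)))
    for (sp in species) map[[sp]] <- genes
    list(utrs = utrs, ortholog_map = map, truth_targets = targets)
  })
}

#' Simulate control and overexpression expression tables
#'
#' Gene baselines are lognormal; every observation carries multiplicative
#' lognormal noise; true targets are repressed `f`-fold in the treatment
#' (treatment mean = control mean / f), so their expected log2 fold change
#' is `-log2(f)`.
#'
#' @param genes Character vector of gene ids.
#' @param targets Character vector of true target genes (subset of
#'   `genes`).
#' @param f Repression factor (>= 1; 1 is the null).
#' @param sd Noise standard deviation on the natural-log scale.
#' @param n_control,n_treatment Replicates per condition.
#' @param baseline_meanlog,baseline_sdlog Lognormal baseline parameters.
#' @param seed Optional RNG seed.
#' @return A list of two expression tibbles, `control` and `treatment`.
#' @export
simulate_expression <- function(genes, targets, f = 1.3, sd = 0.25,
                                n_control = 2, n_treatment = 2,
                                baseline_meanlog = log(100),
                                baseline_sdlog = 1, seed = NULL) {
  if (f < 1) abort("repression factor f must be >= 1")
  if (length(setdiff(targets, genes))) abort("targets must be a subset of genes")
  with_seed_if(seed, {
    mu <- rlnorm(length(genes), baseline_meanlog, baseline_sdlog)
    mu_t <- ifelse(genes %in% targets, mu / f, mu)
    noise <- function(m, n) {
      vapply(seq_len(n), function(i) m * exp(rnorm(length(m), 0, sd)),
             numeric(length(m)))
    }
    ctrl <- as_tibble(noise(mu, n_control), .name_repair = ~ paste0("ctrl", seq_len(n_control)))
    trt <- as_tibble(noise(mu_t, n_treatment), .name_repair = ~ paste0("trt", seq_len(n_treatment)))
    list(control = bind_cols(tibble(gene = genes), ctrl),
         treatment = bind_cols(tibble(gene = genes), trt))
  })
}
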