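# Cross-species target-set overlap through one-to-one ortholog tuples:
# pairwise and pooled overlap, member attribution of shared genes, and the
# targeted fraction of a transcriptome.

#' Project a gene set into ortholog-tuple space
#'
#' Genes without an ortholog tuple in the map are dropped from the
#' projection (they still count in species-specific set sizes downstream).
#'
#' @param genes Character vector of gene ids in one species.
#' @param map Ortholog map tibble: a `tuple` column plus one column per
#'   species (see [read_ortholog_map()]).
#' @param species Which species column the genes belong to.
#' @return A tibble with columns `tuple`, `gene`.
#' @export
project_orthologs <- function(genes, map, species) {
  if (!species %in% names(map)) abort(paste0("species '", species, "' not in ortholog map"))
  hit <- map[!is.na(map[[species]]) & map[[species]] %in% genes, ]
  tibble(tuple = hit$tuple, gene = hit[[species]])
}

# unique keys for overlap arithmetic: ortholog tuple id when mapped,
# otherwise a species-private key (unmapped genes can never be shared)
overlap_keys <- function(genes, map, species) {
  proj <- project_orthologs(genes, map, species)
  mapped <- proj$tuple
  unmapped <- setdiff(genes, proj$gene)
  if (!length(unmapped)) return(mapped)
  c(mapped, paste0(species, "::", unmapped))
}

#' Cross-species overlap of two target sets
#'
#' Shared genes are counted in ortholog-tuple space; the percentage
#' convention is shared over the union (unmapped genes stay in the union
#' as species-private elements), alongside per-species percentages
#' (shared over each species' set size).
#'
#' @param a,b Character vectors of target genes (or tibbles with a `gene`
#'   column) in the two species.
#' @param map Ortholog map tibble.
#' @param species Length-2 character vector naming the species of `a` and
#'   `b`.
#' @param scope Label for the compared sets (a member id or `"pooled"`).
#' @return A one-row tibble: `scope`, `species_a`, `species_b`, `size_a`,
#'   `size_b`, `shared`, `union`, `pct_union`, `pct_a`, `pct_b`, and
#'   `shared_tuples` (list column).
#' @export
pairwise_overlap <- function(a, b, map, species, scope = "member") {
  if (is.data.frame(a)) a <- a$gene
  if (is.data.frame(b)) b <- b$gene
  a <- unique(a); b <- unique(b)
  ka <- overlap_keys(a, map, species[1])
  kb <- overlap_keys(b, map, species[2])
  shared_keys <- intersect(ka, kb)
  uni <- union(ka, kb)
  n_sh <- length(shared_keys)
  tibble(scope = scope,
         species_a = species[1], species_b = species[2],
         size_a = length(a), size_b = length(b),
         shared = n_sh, union = length(uni),
         pct_union = if (length(uni)) n_sh / length(uni) * 100 else 0,
         pct_a = if (length(a)) n_sh / length(a) * 100 else 0,
         pct_b = if (length(b)) n_sh / length(b) * 100 else 0,
         shared_tuples = list(shared_keys))
}

#' Overlap of target sets across two or more species
#'
#' Generalization of [pairwise_overlap()]: `shared` counts ortholog tuples
#' targeted in every species, `union` counts distinct elements across all.
#'
#' @param sets Named list of gene-id vectors, one per species.
#' @param map Ortholog map tibble.
#' @param scope Label for the compared sets.
#' @return A one-row tibble with `scope`, `n_species`, `shared`, `union`,
#'   `pct_union`, `sizes` and `shared_tuples` (list columns).
#' @export
multi_overlap <- function(sets, map, scope = "member") {
  stopifnot(length(sets) >= 2, !is.null(names(sets)))
  keys <- purrr::imap(sets, function(g, sp) overlap_keys(unique(g), map, sp))
  shared_keys <- purrr::reduce(keys, intersect)
  uni <- purrr::reduce(keys, union)
  n_sh <- length(shared_keys)
  tibble(scope = scope, n_species = length(sets),
         shared = n_sh, union = length(uni),
         pct_union = if (length(uni)) n_sh / length(uni) * 100 else 0,
         sizes = list(vapply(sets, function(g) length(unique(g)), 0L)),
         shared_tuples = list(shared_keys))
}

#' Pooled-cluster overlap with member attribution
#'
#' Pools the per-member target sets within each species (their union) and
#' compares the pooled sets across species.  For every shared ortholog
#' tuple the members targeting it in each species are reported, exposing
#' targets that are retained by the cluster while handed over between
#' members.
#'
#' @param targets Tibble with columns `species`, `member`, `gene`
#'   (per-member target sets; any `member == "pooled"` rows are ignored).
#' @param map Ortholog map tibble.
#' @param species Length-2 character vector of species to compare;
#'   defaults to the two species in `targets`.
#' @return The [pairwise_overlap()] row (scope `"pooled"`) with an extra
#'   list column `shared_members`: a tibble `tuple`, `species`, `member`.
#' @export
pooled_overlap <- function(targets, map, species = NULL) {
  stopifnot(all(c("species", "member", "gene") %in% names(targets)))
  targets <- filter(targets, .data$member != "pooled")
  if (is.null(species)) species <- unique(targets$species)
  if (length(species) != 2) abort("pooled_overlap compares exactly two species")
  sets <- lapply(species, function(sp) unique(targets$gene[targets$species == sp]))
  res <- pairwise_overlap(sets[[1]], sets[[2]], map, species, scope = "pooled")
  shared <- res$shared_tuples[[1]]
  attribution <- purrr::map_dfr(species, function(sp) {
    proj <- project_orthologs(unique(targets$gene[targets$species == sp]), map, sp)
    proj <- proj[proj$tuple %in% shared, ]
    if (nrow(proj) == 0) return(NULL)
    tg <- targets[targets$species == sp, ]
    purrr::map_dfr(seq_len(nrow(proj)), function(i) {
      tibble(tuple = proj$tuple[i], species = sp,
             member = sort(unique(tg$member[tg$gene == proj$gene[i]])))
    })
  })
  res$shared_members <- list(attribution)
  res
}

#' Fraction of a transcriptome covered by a target set
#'
#' @param targets Character vector of target genes (subset of
#'   `transcriptome`).
#' @param transcriptome Character vector of expressed genes.
#' @return Percentage `|targets| / |transcriptome| * 100`.
#' @export
target_fraction <- function(targets, transcriptome) {
  transcriptome <- unique(transcriptome)
  if (!length(transcriptome)) abort("empty transcriptome")
  targets <- unique(targets)
  if (length(setdiff(targets, transcriptome))) {
    abort("target set must be a subset of the transcriptome")
  }
  length(targets) / length(transcriptome) * 100
}
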