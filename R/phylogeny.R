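# Dollo dating of cluster members on a species tree: origin at the MRCA of
# expression-verified bearers, losses as the minimal branch set silencing
# the non-bearers, plus the new/old classification against a reference
# split and genomic sub-cluster grouping.

# tip labels descending from a node (tips included)
descendant_tips <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(tree$tip.label[node])
  kids <- descendant_nodes(tree, node)
  tree$tip.label[kids[kids <= n_tip]]
}

# all descendant nodes of `node` (excluding itself), simple BFS on the edge
# matrix so we do not depend on phangorn at run time
descendant_nodes <- function(tree, node) {
  out <- integer(0)
  frontier <- node
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% frontier, 2]
    if (!length(kids)) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

node_label <- function(tree, node) {
  n_tip <- ape::Ntip(tree)
  if (node <= n_tip) return(tree$tip.label[node])
  lab <- NULL
  if (!is.null(tree$node.label)) lab <- tree$node.label[node - n_tip]
  if (!is.null(lab) && !is.na(lab) && nzchar(lab)) return(lab)
  paste(sort(descendant_tips(tree, node)), collapse = "|")
}

resolve_node <- function(tree, node) {
  if (is.numeric(node)) return(as.integer(node))
  n_tip <- ape::Ntip(tree)
  if (node %in% tree$tip.label) return(match(node, tree$tip.label))
  if (!is.null(tree$node.label) && node %in% tree$node.label) {
    return(n_tip + match(node, tree$node.label))
  }
  all_nodes <- seq_len(n_tip + tree$Nnode)
  labs <- vapply(all_nodes, function(v) node_label(tree, v), "")
  hit <- match(node, labs)
  if (is.na(hit)) abort(paste0("node '", node, "' not found in tree"))
  hit
}

#' Infer the origination node of a cluster member
#'
#' The member is assumed to have emerged in the most recent common ancestor
#' of all species with verified expression (the Dollo gain placement).  A
#' member verified in a single species maps to that leaf (its terminal
#' branch).
#'
#' @param tree A rooted `phylo` tree.
#' @param species_present Character vector of species with verified
#'   expression of the member.
#' @return The node number of the origin (a tip number for single-species
#'   members).
#' @export
infer_origin <- function(tree, species_present) {
  if (length(species_present) < 1) abort("member has no verified species")
  missing <- setdiff(species_present, tree$tip.label)
  if (length(missing)) {
    abort(paste0("verified species not in tree: ", paste(missing, collapse = ", ")))
  }
  if (length(unique(species_present)) == 1) {
    return(match(species_present[1], tree$tip.label))
  }
  ape::getMRCA(tree, unique(species_present))
}

#' Infer the minimal loss branches under an origin
#'
#' Standard Dollo minimization: the loss branches are the stems of the
#' maximal subtrees under the origin whose scored leaves are all absent.
#' Leaves not listed in `presence` are treated as unscored and never force
#' or block a loss.
#'
#' @param tree A rooted `phylo` tree.
#' @param origin Origin node (number or label) from [infer_origin()].
#' @param presence Named logical vector over species (tree leaves).
#' @return Integer vector of child-node numbers identifying the loss
#'   branches (the branch above each returned node).
#' @export
infer_losses <- function(tree, origin, presence) {
  origin <- resolve_node(tree, origin)
  n_tip <- ape::Ntip(tree)
  scored <- names(presence)
  # per node: number of scored TRUE / scored FALSE leaves below (tips incl.)
  count_leaves <- function(node) {
    tips <- descendant_tips(tree, node)
    tips <- tips[tips %in% scored]
    c(true = sum(presence[tips]), false = sum(!presence[tips]))
  }
  if (origin <= n_tip) return(integer(0))
  losses <- integer(0)
  frontier <- tree$edge[tree$edge[, 1] == origin, 2]
  while (length(frontier)) {
    node <- frontier[1]
    frontier <- frontier[-1]
    cnt <- count_leaves(node)
    if (cnt["true"] == 0 && cnt["false"] > 0) {
      losses <- c(losses, node)        # maximal all-absent subtree
    } else if (cnt["false"] > 0) {
      frontier <- c(frontier, tree$edge[tree$edge[, 1] == node, 2])
    }
  }
  sort(losses)
}

#' Classify a member as new or old against a reference split
#'
#' A member is "new" when its origin lies within the subtree rooted at the
#' ingroup-side child of the reference split (the child itself included);
#' otherwise it is "old".
#'
#' @param tree A rooted `phylo` tree.
#' @param origin Origin node (number or label).
#' @param reference_split Node of the split (number or label); defaults to
#'   the root.
#' @param ingroup_tip A tip name inside the ingroup-side child clade.
#' @return `"new"` or `"old"`.
#' @export
classify_age <- function(tree, origin, reference_split = NULL, ingroup_tip) {
  origin <- resolve_node(tree, origin)
  n_tip <- ape::Ntip(tree)
  split <- if (is.null(reference_split)) n_tip + 1L else resolve_node(tree, reference_split)
  if (!ingroup_tip %in% tree$tip.label) abort("ingroup_tip not in tree")
  kids <- tree$edge[tree$edge[, 1] == split, 2]
  if (!length(kids)) abort("reference_split is a leaf; it has no child clades")
  ingroup_child <- NA_integer_
  for (k in kids) {
    if (ingroup_tip %in% descendant_tips(tree, k)) ingroup_child <- k
  }
  if (is.na(ingroup_child)) abort("ingroup_tip is not below reference_split")
  inside <- c(ingroup_child, descendant_nodes(tree, ingroup_child))
  if (origin %in% inside) "new" else "old"
}

#' Date origination, losses and age class for every member
#'
#' Tidy wrapper running [infer_origin()], [infer_losses()] and
#' [classify_age()] across a presence matrix.
#'
#' @param presence Long tibble with columns `member`, `species`, `present`.
#' @param tree A rooted `phylo` tree.
#' @param reference_split,ingroup_tip Passed to [classify_age()]; when
#'   `ingroup_tip` is `NULL` the age class is not computed.
#' @return A tibble with one row per member: `origin_node`, `origin_label`,
#'   `n_species`, `losses` (list of branch labels), `n_losses`,
#'   `age_class`.
#' @export
date_origins <- function(presence, tree, reference_split = NULL,
                         ingroup_tip = NULL) {
  stopifnot(all(c("member", "species", "present") %in% names(presence)))
  purrr::map_dfr(unique(presence$member), function(m) {
    pm <- presence[presence$member == m, ]
    pvec <- setNames(pm$present, pm$species)
    sp_true <- names(pvec)[pvec]
    if (!length(sp_true)) {
      return(tibble(member = m, origin_node = NA_integer_,
                    origin_label = NA_character_, n_species = 0L,
                    losses = list(character(0)), n_losses = 0L,
                    age_class = NA_character_))
    }
    origin <- infer_origin(tree, sp_true)
    losses <- infer_losses(tree, origin, pvec)
    age <- if (is.null(ingroup_tip)) NA_character_ else {
      classify_age(tree, origin, reference_split, ingroup_tip)
    }
    loss_labels <- vapply(losses, function(v) node_label(tree, v), "")
    tibble(member = m,
           origin_node = origin,
           origin_label = node_label(tree, origin),
           n_species = length(sp_true),
           losses = list(loss_labels),
           n_losses = length(loss_labels),
           age_class = age)
  })
}

#' Group cluster loci into genomic sub-clusters
#'
#' Single-linkage chaining of loci on one chromosome and strand: adjacent
#' loci with an inter-locus gap of at most `max_gap` nt join the same
#' sub-cluster.  Overlapping loci raise a warning and are treated as gap 0.
#' Singleton groups are flagged as orphans.
#'
#' @param loci Tibble with columns `member`, `start`, `end` (0-based
#'   half-open) and optionally `chrom`, `strand` (must be constant).
#' @param max_gap Maximum chaining gap in nt (default 1000).
#' @return The input ordered by `start`, with `subcluster` (integer) and
#'   `orphan` (logical) columns added.
#' @export
subcluster <- function(loci, max_gap = 1000) {
  stopifnot(all(c("member", "start", "end") %in% names(loci)))
  if ("chrom" %in% names(loci) && length(unique(loci$chrom)) > 1) {
    abort("sub-clustering expects loci on a single chromosome")
  }
  if ("strand" %in% names(loci) && length(unique(loci$strand)) > 1) {
    abort("sub-clustering expects loci on a single strand")
  }
  loci <- arrange(loci, .data$start)
  gaps <- loci$start[-1] - utils::head(loci$end, -1)
  if (any(gaps < 0)) {
    warn("overlapping loci; treating their gap as 0")
    gaps <- pmax(gaps, 0)
  }
  grp <- cumsum(c(1L, as.integer(gaps > max_gap)))
  loci$subcluster <- grp
  loci %>%
    group_by(.data$subcluster) %>%
    mutate(orphan = n() == 1L) %>%
    ungroup()
}
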