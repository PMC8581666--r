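# Dominant mature products, seed extraction, classification of
# inter-species seed innovations (arm switching vs seed shifting vs
# substitution) and Fitch-parsimony placement of the events on branches.

#' Extract the seed from a mature miRNA sequence
#'
#' The seed is nucleotides 2-8 (1-based) of the mature sequence: the 7-mer
#' governing canonical target recognition.
#'
#' @param mature_seq Mature sequence (>= 8 nt, RNA or DNA alphabet).
#' @return The 7-nt seed (RNA alphabet).
#' @export
extract_seed <- function(mature_seq) {
  mature_seq <- normalize_rna(mature_seq)
  if (any(nchar(mature_seq) < 8)) abort("mature sequence must be at least 8 nt for seed extraction")
  substr(mature_seq, 2, 8)
}

#' Determine the dominant mature product of a hairpin
#'
#' The dominant product is the highest-count isomiR (unique `(start,
#' length)` read); ties are broken by lower start, then shorter length.
#' The arm is called from the read's position relative to the hairpin loop
#' (the region enclosed by the innermost base pair).  Equal top counts on
#' the two arms, or reads confined to the loop, are errors demanding manual
#' resolution.
#'
#' @param profile Tibble with columns `start`, `length`, `count` for one
#'   hairpin.
#' @param fold A `hairpin_fold` of the precursor.
#' @param species,member Optional labels carried into the result.
#' @return A one-row tibble: `species`, `member`, `arm`, `start`, `length`,
#'   `mature_seq`, `seed`.
#' @export
dominant_mature <- function(profile, fold, species = NA_character_,
                            member = NA_character_) {
  stopifnot(inherits(fold, "hairpin_fold"))
  if (nrow(profile) == 0) abort("empty read profile")
  paired <- which(!is.na(fold$pairs) & seq_len(fold$n) < fold$pairs)
  if (!length(paired)) abort("unstructured precursor: cannot assign arms")
  inner5 <- max(paired)           # innermost pair bounds the loop
  inner3 <- fold$pairs[inner5]
  iso <- profile %>%
    group_by(.data$start, .data$length) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(mid = .data$start + .data$length / 2,
           arm = case_when(.data$mid <= inner5 ~ "5p",
                           .data$mid >= inner3 ~ "3p",
                           TRUE ~ "loop")) %>%
    filter(.data$arm != "loop")
  if (nrow(iso) == 0) abort("reads only in the loop region: no arm product")
  top <- max(iso$count)
  top_arms <- unique(iso$arm[iso$count == top])
  if (length(top_arms) > 1) {
    abort("tie between arms for the dominant product; resolve manually")
  }
  dom <- iso %>%
    arrange(desc(.data$count), .data$start, .data$length) %>%
    slice(1)
  mature <- substr(fold$seq, dom$start + 1, dom$start + dom$length)
  tibble(species = species, member = member, arm = dom$arm,
         start = dom$start, length = dom$length,
         mature_seq = mature, seed = extract_seed(mature))
}

#' Classify the seed difference between two species' assignments
#'
#' For one member observed in two species: different arms give
#' `arm_switch`; on the same arm, a seed reachable as a processing-register
#' shift of at most 5 nt along the partner's mature sequence gives
#' `seed_shift`; seeds differing in place give `substitution` (with a
#' warning when the offset also moved beyond the shift window); identical
#' arms and seeds give `none`.
#'
#' @param a,b One-row tibbles (or lists) with `arm`, `start`, `mature_seq`,
#'   `seed`, and optionally `member`.
#' @param max_shift Largest processing shift (nt) still called a seed
#'   shift.
#' @return One of `"none"`, `"arm_switch"`, `"seed_shift"`,
#'   `"substitution"`.
#' @export
classify_change <- function(a, b, max_shift = 5) {
  if (!is.null(a[["member"]]) && !is.null(b[["member"]]) &&
      !is.na(a[["member"]]) && !is.na(b[["member"]]) && a[["member"]] != b[["member"]]) {
    abort("classify_change compares one member across species")
  }
  if (a$arm != b$arm) return("arm_switch")
  if (a$seed == b$seed) return("none")
  shifted <- function(x, y) {
    # y's seed found at a shifted register of x's mature sequence
    for (s in setdiff(-max_shift:max_shift, 0)) {
      lo <- 2 + s
      if (lo < 1 || lo + 6 > nchar(x$mature_seq)) next
      if (substr(x$mature_seq, lo, lo + 6) == y$seed) return(TRUE)
    }
    FALSE
  }
  if (shifted(a, b) || shifted(b, a)) return("seed_shift")
  if (!is.null(a[["start"]]) && !is.null(b[["start"]]) && a[["start"]] != b[["start"]]) {
    warn("seeds differ at shifted offsets beyond the shift window; classified as substitution")
  }
  "substitution"
}

# enumerate all minimum-change labelings of internal nodes over the
# observed states; returns list(score, labelings); trees here are small
enumerate_parsimony <- function(tree, tip_states) {
  n_tip <- ape::Ntip(tree)
  states <- unique(unname(tip_states))
  internal <- n_tip + seq_len(tree$Nnode)
  grids <- rep(list(states), length(internal))
  combos <- expand.grid(grids, stringsAsFactors = FALSE)
  costs <- apply(combos, 1, function(row) {
    lab <- as.character(row)
    full <- c(setNames(tip_states[tree$tip.label], seq_len(n_tip)),
              setNames(lab, internal))
    sum(full[as.character(tree$edge[, 1])] != full[as.character(tree$edge[, 2])])
  })
  score <- min(costs)
  labelings <- lapply(which(costs == score), function(r) {
    setNames(as.character(combos[r, ]), internal)
  })
  list(score = score, labelings = labelings)
}

#' Place seed-innovation events on tree branches by parsimony
#'
#' The composite state `(arm, seed)` of one member across species is
#' mapped on the tree restricted to the species bearing the member; all
#' minimum-change ancestral labelings are enumerated and every state change
#' is reported as an event together with the branch(es) it may lie on.
#' When parsimony cannot localize a change to one branch, `resolved` is
#' `FALSE` and `branches` lists all candidates.
#'
#' @param assignments Tibble with columns `species`, `arm`, `seed` (and
#'   optionally `start`, `mature_seq`, used to refine the event type) for
#'   one member.
#' @param tree A rooted `phylo` tree containing those species.
#' @return A tibble with one row per event: `type`, `state_a`, `state_b`,
#'   `branches` (list of branch labels, each the clade below the branch),
#'   `resolved`.  Zero rows when all states agree or only one species is
#'   assigned.  The Fitch parsimony score is attached as attribute
#'   `score`.
#' @export
place_events <- function(assignments, tree) {
  stopifnot(all(c("species", "arm", "seed") %in% names(assignments)))
  sp <- assignments$species
  if (anyDuplicated(sp)) abort("one assignment per species expected")
  if (length(sp) < 2) {
    out <- tibble(type = character(), state_a = character(),
                  state_b = character(), branches = list(), resolved = logical())
    attr(out, "score") <- 0L
    return(out)
  }
  missing <- setdiff(sp, tree$tip.label)
  if (length(missing)) abort(paste0("species not in tree: ", missing[1]))
  sub <- ape::keep.tip(tree, sp)
  states <- setNames(paste(assignments$arm, assignments$seed, sep = ":"), sp)
  if (length(unique(states)) == 1) {
    out <- tibble(type = character(), state_a = character(),
                  state_b = character(), branches = list(), resolved = logical())
    attr(out, "score") <- 0L
    return(out)
  }
  enum <- enumerate_parsimony(sub, states)
  n_tip <- ape::Ntip(sub)
  branch_label <- function(child) paste(sort(descendant_tips(sub, child)), collapse = "|")

  changes <- purrr::imap_dfr(enum$labelings, function(lab, li) {
    full <- c(setNames(unname(states[sub$tip.label]), seq_len(n_tip)), lab)
    e <- sub$edge
    from <- full[as.character(e[, 1])]
    to <- full[as.character(e[, 2])]
    idx <- which(from != to)
    tibble(labeling = li,
           pair = vapply(idx, function(k) paste(sort(c(from[k], to[k])), collapse = "~"), ""),
           branch = vapply(e[idx, 2], branch_label, ""))
  })

  rep_assign <- function(state) {
    i <- match(state, unname(states))
    assignments[i, , drop = FALSE]
  }
  first <- changes[changes$labeling == 1, ]
  events <- purrr::map_dfr(unique(first$pair), function(p) {
    k <- sum(first$pair == p)
    cand <- sort(unique(changes$branch[changes$pair == p]))
    per_lab <- changes %>%
      filter(.data$pair == p) %>%
      group_by(.data$labeling) %>%
      summarise(set = paste(sort(.data$branch), collapse = ","),
                nn = n(), .groups = "drop")
    consistent <- length(unique(per_lab$set)) == 1 &&
      all(per_lab$nn == k) &&
      length(unique(changes$labeling)) == length(enum$labelings) &&
      nrow(per_lab) == length(enum$labelings)
    st <- strsplit(p, "~", fixed = TRUE)[[1]]
    a <- rep_assign(st[1]); b <- rep_assign(st[2])
    type <- if (sub(":.*", "", st[1]) != sub(":.*", "", st[2])) {
      "arm_switch"
    } else if (all(c("start", "mature_seq") %in% names(assignments))) {
      classify_change(a, b)
    } else {
      "seed_change"   # register unknown without the mature sequences
    }
    tibble(type = type, state_a = st[1], state_b = st[2],
           branches = rep(list(cand), k),
           resolved = rep(consistent && length(cand) == k, k))
  })
  attr(events, "score") <- enum$score
  events
}
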