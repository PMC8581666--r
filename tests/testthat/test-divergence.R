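test_that("ortholog projection keeps mapped genes only", {
  map <- tibble::tibble(tuple = c("og1", "og2", "og3"),
                        mel = c("gA", "gB", "gC"),
                        sim = c("hA", "hB", NA))
  proj <- project_orthologs(c("gA", "gC", "gX"), map, "mel")
  expect_equal(proj$tuple, c("og1", "og3"))
  expect_equal(nrow(project_orthologs(character(0), map, "sim")), 0)
  expect_error(project_orthologs("gA", map, "yak"), "not in ortholog map")
})

test_that("overlap arithmetic uses the shared-over-union convention", {
  genes <- paste0("g", 1:100)
  map <- identity_map(genes, c("mel", "sim"))
  a <- paste0("g", 1:36)
  b <- paste0("g", 31:65)             # shared: g31..g36
  ov <- pairwise_overlap(a, b, map, c("mel", "sim"))
  expect_equal(ov$shared, 6)
  expect_equal(ov$union, 65)
  expect_equal(round(ov$pct_union, 1), 9.2)
  expect_equal(pairwise_overlap(a, a, map, c("mel", "sim"))$pct_union, 100)
  expect_equal(pairwise_overlap(a, paste0("g", 71:80), map,
                                c("mel", "sim"))$pct_union, 0)
  # permutation invariance
  ba <- pairwise_overlap(b, a, map, c("sim", "mel"))
  expect_equal(ba$pct_union, ov$pct_union)
  expect_equal(ba$shared, ov$shared)
  # invariant: union percentage never exceeds the per-species ones
  expect_lte(ov$pct_union, min(ov$pct_a, ov$pct_b))
})

test_that("unmapped genes count in sizes and union but never in shared", {
  map <- tibble::tibble(tuple = c("og1", "og2"),
                        mel = c("g1", "g2"), sim = c("h1", "h2"))
  ov <- pairwise_overlap(c("g1", "g9"), c("h1", "h9"), map, c("mel", "sim"))
  expect_equal(ov$shared, 1)
  expect_equal(ov$union, 3)            # og1 + two species-private genes
  expect_equal(ov$size_a, 2)
  # empty map: shared always 0
  empty <- tibble::tibble(tuple = character(), mel = character(), sim = character())
  expect_equal(pairwise_overlap("g1", "h1", empty, c("mel", "sim"))$shared, 0)
})

test_that("pooled overlap attributes shared genes to members per species", {
  genes <- paste0("g", 1:20)
  map <- identity_map(genes, c("mel", "sim"))
  targets <- dplyr::bind_rows(
    tibble::tibble(species = "mel", member = "m1", gene = c("g1", "g2")),
    tibble::tibble(species = "mel", member = "m2", gene = c("g3")),
    tibble::tibble(species = "sim", member = "m1", gene = c("g1", "g9")),
    tibble::tibble(species = "sim", member = "m2", gene = c("g2")))
  ov <- pooled_overlap(targets, map)
  # g2 is shared by the cluster though no single member shares it
  expect_equal(ov$shared, 2)
  att <- ov$shared_members[[1]]
  g2 <- att[att$tuple == "og2", ]
  expect_equal(g2$member[g2$species == "mel"], "m1")
  expect_equal(g2$member[g2$species == "sim"], "m2")
  # per-member shared counts are strictly below the pooled one here
  m1 <- pairwise_overlap(targets$gene[targets$member == "m1" & targets$species == "mel"],
                         targets$gene[targets$member == "m1" & targets$species == "sim"],
                         map, c("mel", "sim"))
  m2 <- pairwise_overlap(targets$gene[targets$member == "m2" & targets$species == "mel"],
                         targets$gene[targets$member == "m2" & targets$species == "sim"],
                         map, c("mel", "sim"))
  expect_gt(ov$shared, m1$shared + m2$shared)
  # single member: pooled equals the member's pairwise result
  ov1 <- pooled_overlap(targets[targets$member == "m1", ], map)
  expect_equal(ov1$shared, m1$shared)
  expect_equal(ov1$pct_union, m1$pct_union)
})

test_that("pooled shared tuples contain every per-member shared tuple (fuzz)", {
  withr::with_seed(404, {
    genes <- paste0("g", 1:30)
    map <- identity_map(genes, c("a", "b"))
    for (i in 1:20) {
      targets <- purrr::map_dfr(c("a", "b"), function(sp) {
        purrr::map_dfr(c("m1", "m2", "m3"), function(m) {
          tibble::tibble(species = sp, member = m,
                         gene = sample(genes, sample(3:10, 1)))
        })
      })
      pooled <- pooled_overlap(targets, map, species = c("a", "b"))
      member_shared <- unlist(lapply(c("m1", "m2", "m3"), function(m) {
        pairwise_overlap(targets$gene[targets$member == m & targets$species == "a"],
                         targets$gene[targets$member == m & targets$species == "b"],
                         map, c("a", "b"))$shared_tuples[[1]]
      }))
      expect_true(all(member_shared %in% pooled$shared_tuples[[1]]))
    }
  })
})

test_that("three-way overlaps obey inclusion-exclusion", {
  withr::with_seed(505, {
    genes <- paste0("g", 1:25)
    map <- identity_map(genes, c("a", "b", "c"))
    for (i in 1:10) {
      sets <- list(a = sample(genes, 12), b = sample(genes, 12),
                   c = sample(genes, 12))
      triple <- multi_overlap(sets, map)
      pair <- function(x, y) length(intersect(sets[[x]], sets[[y]]))
      uni <- triple$union
      manual <- length(unique(unlist(sets)))
      expect_equal(uni, manual)
      expect_equal(triple$shared,
                   length(intersect(intersect(sets$a, sets$b), sets$c)))
      incl_excl <- sum(lengths(sets)) - pair("a", "b") - pair("a", "c") -
        pair("b", "c") + triple$shared
      expect_equal(uni, incl_excl)
    }
  })
})

test_that("target fraction is a simple percentage with guards", {
  expect_equal(target_fraction(paste0("g", 1:211), paste0("g", 1:1000)), 21.1)
  expect_equal(target_fraction(character(0), paste0("g", 1:10)), 0)
  expect_equal(target_fraction(paste0("g", 1:10), paste0("g", 1:10)), 100)
  expect_error(target_fraction("g1", character(0)), "empty")
  expect_error(target_fraction("gX", paste0("g", 1:10)), "subset")
})
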