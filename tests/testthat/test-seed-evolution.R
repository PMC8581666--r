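test_that("seed extraction takes mature positions 2-8", {
  expect_equal(extract_seed("UAUUGCACUUGAGACGGCCUGA"), "AUUGCAC")
  expect_equal(extract_seed("UAAGGCAC"), "AAGGCAC")
  expect_error(extract_seed("UAAGGCA"), "at least 8")
})

test_that("dominant product selection follows the max-count rule", {
  hp <- make_hairpin("UAUUGCACUUGAGACGGCCUGA")
  fold <- fold_hairpin(hp$seq)
  prof <- tibble::tibble(start = c(hp$mir_start, hp$star_start),
                         length = c(22L, 22L), count = c(500L, 80L))
  dm <- dominant_mature(prof, fold)
  expect_equal(dm$arm, "5p")
  expect_equal(dm$start, hp$mir_start)
  expect_equal(dm$mature_seq, "UAUUGCACUUGAGACGGCCUGA")
  # equal top counts on the same arm: lower start wins
  prof2 <- tibble::tibble(start = c(hp$mir_start, hp$mir_start + 2L),
                          length = c(22L, 22L), count = c(100L, 100L))
  expect_equal(dominant_mature(prof2, fold)$start, hp$mir_start)
  # equal top counts on opposite arms is an error
  prof3 <- tibble::tibble(start = c(hp$mir_start, hp$star_start),
                          length = c(22L, 22L), count = c(100L, 100L))
  expect_error(dominant_mature(prof3, fold), "tie between arms")
  # loop-only reads cannot define a product
  mature <- "UAUUGCACUUGAGACGGCCUGA"
  wide <- paste0(mature, strrep("A", 30), rna_revcomp(mature))
  fwide <- fold_from_dotbracket(wide, paste0(strrep("(", 22), strrep(".", 30),
                                             strrep(")", 22)))
  prof4 <- tibble::tibble(start = 30L, length = 10L, count = 10L)
  expect_error(dominant_mature(prof4, fwide), "loop")
})

test_that("seed-change classification separates the three mechanisms", {
  a <- tibble::tibble(member = "m", arm = "5p", start = 10L,
                      mature_seq = "UAUUGCACUUGAGACGGCCUGA",
                      seed = extract_seed("UAUUGCACUUGAGACGGCCUGA"))
  # arm switch dominates
  b_arm <- dplyr::mutate(a, arm = "3p", seed = "GGGCCAU")
  expect_equal(classify_change(a, b_arm), "arm_switch")
  # processing register shifted by +2 on the same arm
  b_shift <- tibble::tibble(member = "m", arm = "5p", start = 12L,
                            mature_seq = substr(a$mature_seq, 3, 22),
                            seed = substr(a$mature_seq, 4, 10))
  expect_equal(classify_change(a, b_shift), "seed_shift")
  expect_equal(classify_change(b_shift, a), "seed_shift")  # symmetric
  # same register, point-mutated seed
  b_sub <- dplyr::mutate(a, seed = "AUUGCAG")
  expect_equal(classify_change(a, b_sub), "substitution")
  expect_equal(classify_change(a, a), "none")
  expect_error(classify_change(a, dplyr::mutate(b_arm, member = "other")),
               "one member")
})

test_that("event placement reproduces the textbook three-leaf cases", {
  tr <- read_newick("((mel,sim),vir);")
  # mel = sim != vir: one event, two candidate branches, unresolved
  asg <- tibble::tibble(species = c("mel", "sim", "vir"),
                        arm = c("5p", "5p", "3p"),
                        seed = c("AUUGCAC", "AUUGCAC", "GGGCCAU"),
                        start = c(10L, 10L, 48L),
                        mature_seq = c("UAUUGCACUUGAGACGGCCUGA",
                                       "UAUUGCACUUGAGACGGCCUGA",
                                       "GGGGCCAUAUAUGCGCAUUAGC"))
  ev <- place_events(asg, tr)
  expect_equal(nrow(ev), 1)
  expect_equal(attr(ev, "score"), 1L)
  expect_false(ev$resolved)
  expect_setequal(ev$branches[[1]], c("vir", "mel|sim"))
  expect_equal(ev$type, "arm_switch")
  # mel != sim, vir = mel: resolved on the sim terminal branch
  asg2 <- dplyr::mutate(asg,
                        arm = c("5p", "5p", "5p"),
                        seed = c("AUUGCAC", "AUUGCAG", "AUUGCAC"),
                        start = 10L,
                        mature_seq = asg$mature_seq[1])
  asg2$seed[2] <- "AUUGCAG"
  ev2 <- place_events(asg2, tr)
  expect_equal(nrow(ev2), 1)
  expect_true(ev2$resolved)
  expect_equal(ev2$branches[[1]], "sim")
  # all equal: nothing to place
  asg3 <- dplyr::mutate(asg, arm = "5p", seed = "AUUGCAC")
  expect_equal(nrow(place_events(asg3, tr)), 0)
  expect_equal(nrow(place_events(asg[1, ], tr)), 0)
})

test_that("event counts equal the Fitch parsimony score (phangorn oracle)", {
  withr::with_seed(314, {
    for (i in 1:25) {
      n <- sample(4:6, 1)
      tr <- ape::rtree(n, tip.label = paste0("t", 1:n))
      states <- sample(c("5p:AAAAAAA", "5p:CCCCCCC", "3p:GGGGGGG"),
                       n, replace = TRUE)
      asg <- tibble::tibble(species = tr$tip.label,
                            arm = sub(":.*", "", states),
                            seed = sub(".*:", "", states))
      ev <- place_events(asg, tr)
      dat <- phangorn::phyDat(setNames(as.list(match(states, unique(states))),
                                       tr$tip.label),
                              type = "USER", levels = seq_along(unique(states)))
      expect_equal(attr(ev, "score"),
                   as.integer(phangorn::fitch(ape::unroot(tr), dat)))
    }
  })
})

test_that("scheduled seed events are recovered on the branch they occurred", {
  tr <- study_tree()
  base <- tibble::tibble(species = tr$tip.label, arm = "5p",
                         seed = "AUUGCAC", start = 10L,
                         mature_seq = "UAUUGCACUUGAGACGGCCUGA")
  branches <- c("mel", "sim", "pse", "vir", "mel|sim", "mel|pse|sim")
  n_checked <- 0L
  withr::with_seed(55, {
    for (i in 1:100) {
      br <- sample(branches, 1)
      affected <- strsplit(br, "|", fixed = TRUE)[[1]]
      asg <- base
      mut <- sample(c("arm", "sub"), 1)
      if (mut == "arm") {
        asg$arm[asg$species %in% affected] <- "3p"
        asg$seed[asg$species %in% affected] <- "GGGCCAU"
      } else {
        asg$seed[asg$species %in% affected] <- "AUUGCAU"
      }
      ev <- place_events(asg, tr)
      expect_equal(nrow(ev), 1)
      expect_true(br %in% ev$branches[[1]])
      if (ev$resolved) {
        expect_equal(ev$branches[[1]], br)
        n_checked <- n_checked + 1L
      }
    }
  })
  expect_gt(n_checked, 50)   # most schedules are resolvable on this tree
})
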