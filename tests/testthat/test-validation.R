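test_that("base-pair maximization matches exhaustive enumeration", {
  # worked examples
  f <- fold_hairpin("GGGGAAAACCCC")
  expect_equal(f$n_pairs, 4)
  expect_equal(f$dot_bracket, "((((....))))")
  expect_equal(fold_hairpin(strrep("A", 20))$n_pairs, 0)
  # random short sequences against the brute-force oracle
  withr::with_seed(101, {
    for (i in 1:25) {
      s <- paste(sample(c("A", "C", "G", "U"), sample(8:13, 1), replace = TRUE),
                 collapse = "")
      expect_equal(fold_hairpin(s)$n_pairs, brute_max_pairs(s), label = s)
    }
  })
})

test_that("a perfect inverted repeat folds into its full stem", {
  withr::with_seed(7, {
    arm <- paste(sample(c("G", "C"), 15, replace = TRUE), collapse = "")
    s <- paste0(arm, "AAAA", rna_revcomp(arm))
    f <- fold_hairpin(s)
    expect_equal(f$n_pairs, 15)      # one pair per repeat position
    expect_equal(f$pairs[1], nchar(s))
  })
})

test_that("fold refuses N-rich input and dot-bracket override is validated", {
  expect_error(fold_hairpin(paste0(strrep("N", 10), strrep("A", 20))), "20%")
  f <- fold_from_dotbracket("GGGAAAACCC", "(((....)))")
  expect_equal(f$n_pairs, 3)
  expect_error(fold_from_dotbracket("GGGAAAACCC", "(((....))"), "length")
  expect_error(fold_from_dotbracket("GGGAAAACCC", "(((....().")) # unbalanced
  expect_error(fold_from_dotbracket("GGGAAAAGGG", "(((....)))"),
               "non-complementary")
})

test_that("miR* localization gives the 2-nt 3' overhang and is involutive", {
  mature <- "UAUUGCACUUGAGACGGCCUGA"
  s <- paste0(mature, "AAACAAAC", rna_revcomp(mature))   # bare perfect stem
  f <- fold_from_dotbracket(s, paste0(strrep("(", 22), strrep(".", 8),
                                      strrep(")", 22)))
  st <- locate_star(f, 0, 22)
  # partners of positions 0..21 are the 3' arm, shifted by +2
  expect_equal(st$start, 22 + 8 + 2)
  expect_equal(st$end, nchar(s))
  expect_equal(st$arm, "3p")
  st2 <- locate_star(f, st$start, st$end - st$start)
  ov <- min(st2$end, 22) - max(st2$start, 0)
  expect_gte(ov, 18)
  # miR placed in the loop has no duplex
  expect_error(locate_star(f, 22, 8), "no duplex")
  # a pair-maximized fold of the same stem localizes the same arm
  fn <- fold_hairpin(s)
  stn <- locate_star(fn, 0, 22)
  expect_equal(stn$arm, "3p")
  expect_gt(min(stn$end, st$end) - max(stn$start, st$start), 15)
})

test_that("criteria arithmetic follows the constructed-profile examples", {
  hp <- make_hairpin("UAUUGCACUUGAGACGGCCUGA")
  fold <- fold_hairpin(hp$seq)
  prof <- tibble::tibble(
    start = c(hp$mir_start, hp$star_start, 0, 0),
    length = c(22, 22, 20, 18),
    count = c(18L, 3L, 1L, 1L))
  v <- validate_mirna(prof, fold)
  expect_true(v$verdict)
  expect_equal(v$metrics$star_reads, 3)
  expect_equal(v$metrics$duplex_reads, 21)
  expect_equal(v$metrics$top3_fraction, 1.0)
  expect_equal(v$metrics$background_ratio, 21 / 2)
  # one miR read fewer: total 19 < 20 fails criterion 2 only
  prof2 <- prof
  prof2$count[1] <- 16L
  v2 <- validate_mirna(prof2, fold)
  expect_false(v2$criteria[["c2"]])
  expect_false(v2$verdict)
  expect_true(all(v2$criteria[c("c1", "c3", "c5")]))
  # five equal isomiRs: top-3 fraction 0.6 fails criterion 4
  prof3 <- tibble::tibble(
    start = c(hp$mir_start + 0:4, hp$star_start),
    length = c(rep(22L, 5), 22L),
    count = c(rep(10L, 5), 5L))
  v3 <- validate_mirna(prof3, fold, mir = list(start = hp$mir_start,
                                               end = hp$mir_start + 22))
  expect_equal(v3$metrics$top3_fraction, 0.6)
  expect_false(v3$criteria[["c4"]])
})

test_that("verdict is the conjunction of the five criteria (fuzz)", {
  hp <- make_hairpin("UAUUGCACUUGAGACGGCCUGA")
  fold <- fold_hairpin(hp$seq)
  withr::with_seed(42, {
    for (i in 1:40) {
      prof <- simulate_read_profile(hp, depth_mean = sample(c(5, 30, 200), 1),
                                    background_frac = runif(1, 0, 0.6),
                                    star_ratio = sample(c(2, 10, 50), 1))
      if (nrow(prof) == 0) next
      v <- validate_mirna(prof[-1], fold)
      expect_identical(v$verdict, all(v$criteria))
    }
  })
})

test_that("adding duplex reads never flips a criterion from pass to fail", {
  hp <- make_hairpin("UAUUGCACUUGAGACGGCCUGA")
  fold <- fold_hairpin(hp$seq)
  mir <- list(start = hp$mir_start, end = hp$mir_start + 22)
  base <- tibble::tibble(start = c(hp$mir_start, hp$star_start, 0),
                         length = c(22L, 22L, 20L),
                         count = c(18L, 2L, 5L))
  v0 <- validate_mirna(base, fold, mir = mir)
  more <- base
  more$count[1:2] <- more$count[1:2] + 50L   # more canonical miR and miR* reads
  v1 <- validate_mirna(more, fold, mir = mir)
  expect_true(all(v1$criteria[v0$criteria]))
  # extra background cannot rescue criterion 5
  bg_heavy <- base
  bg_heavy$count[3] <- 100L
  v2 <- validate_mirna(bg_heavy, fold, mir = mir)
  expect_false(v2$criteria[["c5"]] && !v0$criteria[["c5"]])
})

test_that("clean deep synthetic profiles pass validation almost surely", {
  hp <- make_hairpin("UAUUGCACUUGAGACGGCCUGA")
  fold <- fold_hairpin(hp$seq)
  pass <- withr::with_seed(2024, {
    vapply(1:200, function(i) {
      prof <- simulate_read_profile(hp, depth_mean = 150, depth_size = 10,
                                    background_frac = 0)
      validate_mirna(prof[-1], fold)$verdict
    }, TRUE)
  })
  expect_gte(mean(pass), 0.99)
})

test_that("validate_profiles summarizes hairpins and honours overrides", {
  hp <- make_hairpin("UAUUGCACUUGAGACGGCCUGA")
  profs <- dplyr::bind_rows(
    simulate_read_profile(hp, hairpin_id = "h1", seed = 5),
    simulate_read_profile(hp, hairpin_id = "h2", seed = 6, depth_mean = 5))
  res <- validate_profiles(profs, tibble::tibble(id = c("h1", "h2"),
                                                 seq = c(hp$seq, hp$seq)))
  expect_equal(nrow(res), 2)
  expect_true(res$verdict[res$hairpin_id == "h1"])
  expect_error(validate_profiles(profs, tibble::tibble(id = "h1", seq = hp$seq)),
               "no precursor")
})
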