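# Expression-based miRNA validation: hairpin folding by base-pair
# maximization, miR* localization from the duplex, and the five read-profile
# criteria (miR* evidence, read depth, duplex pairing, isomiR concentration,
# signal-to-background ratio).

#' Fold a hairpin precursor by base-pair maximization
#'
#' Dynamic programming over Watson-Crick plus G·U wobble pairs with a
#' minimum hairpin loop of 3 nt (no pair `(i, j)` with `j - i < 4`).  The
#' returned structure maximizes the number of base pairs; it is used for
#' duplex pair counting, not free-energy prediction.  A pre-computed
#' dot-bracket string can be supplied instead via [fold_from_dotbracket()].
#'
#' @param seq Precursor sequence (RNA or DNA alphabet; normalized to RNA).
#' @param id Precursor id carried through to the result.
#' @return An object of class `hairpin_fold`: a list with `id`, `seq`,
#'   `n`, `pairs` (integer vector; `pairs[i]` is the 1-based partner of
#'   position `i`, `NA` if unpaired), `n_pairs` and `dot_bracket`.
#' @export
fold_hairpin <- function(seq, id = "hairpin") {
  seq <- normalize_rna(seq, id)
  n <- nchar(seq)
  b <- strsplit(seq, "")[[1]]
  if (mean(b == "N") > 0.2) {
    abort(paste0("precursor '", id, "' has N at more than 20% of positions"))
  }
  ok_pair <- matrix(FALSE, 5, 5,
                    dimnames = list(c("A", "C", "G", "U", "N"),
                                    c("A", "C", "G", "U", "N")))
  ok_pair["A", "U"] <- ok_pair["U", "A"] <- TRUE
  ok_pair["C", "G"] <- ok_pair["G", "C"] <- TRUE
  ok_pair["G", "U"] <- ok_pair["U", "G"] <- TRUE
  canp <- ok_pair[b, b, drop = FALSE]

  N <- matrix(0L, n, n)
  if (n >= 5) {
    for (span in 4:(n - 1)) {
      for (i in seq_len(n - span)) {
        j <- i + span
        best <- N[i, j - 1L]
        ks <- i:(j - 4L)
        ks <- ks[canp[ks, j]]
        if (length(ks)) {
          left <- ifelse(ks == i, 0L, N[cbind(pmax(i, 1L), pmax(ks - 1L, 1L))])
          left[ks == i] <- 0L
          right <- N[cbind(ks + 1L, j - 1L)]
          best <- max(best, max(left + right + 1L))
        }
        N[i, j] <- best
      }
    }
  }

  pairs <- rep(NA_integer_, n)
  # iterative traceback; prefers the smallest admissible partner for j
  stack <- list(c(1L, n))
  while (length(stack)) {
    ij <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- ij[1]; j <- ij[2]
    while (j - i >= 4L && N[i, j] > 0L) {
      if (N[i, j] == N[i, j - 1L]) {
        j <- j - 1L
        next
      }
      ks <- i:(j - 4L)
      ks <- ks[canp[ks, j]]
      done <- FALSE
      for (k in ks) {
        left <- if (k > i) N[i, k - 1L] else 0L
        if (left + N[k + 1L, j - 1L] + 1L == N[i, j]) {
          pairs[k] <- j
          pairs[j] <- k
          if (k > i) stack[[length(stack) + 1L]] <- c(i, k - 1L)
          i <- k + 1L
          j <- j - 1L
          done <- TRUE
          break
        }
      }
      if (!done) j <- j - 1L
    }
  }

  db <- rep(".", n)
  paired <- which(!is.na(pairs) & seq_len(n) < pairs)
  db[paired] <- "("
  db[pairs[paired]] <- ")"
  structure(list(id = id, seq = seq, n = n, pairs = pairs,
                 n_pairs = length(paired),
                 dot_bracket = paste(db, collapse = "")),
            class = "hairpin_fold")
}

#' Build a hairpin fold from a dot-bracket string
#'
#' Override for [fold_hairpin()] when a structure from another folding
#' backend is available.
#'
#' @param seq Precursor sequence.
#' @param dot_bracket Dot-bracket string of the same length.
#' @param id Precursor id.
#' @return A `hairpin_fold` object.
#' @export
fold_from_dotbracket <- function(seq, dot_bracket, id = "hairpin") {
  seq <- normalize_rna(seq, id)
  n <- nchar(seq)
  if (nchar(dot_bracket) != n) abort("dot-bracket length differs from sequence length")
  ch <- strsplit(dot_bracket, "")[[1]]
  if (any(!ch %in% c("(", ")", "."))) abort("dot-bracket may contain only '(', ')' and '.'")
  pairs <- rep(NA_integer_, n)
  stk <- integer(0)
  for (i in seq_len(n)) {
    if (ch[i] == "(") {
      stk <- c(stk, i)
    } else if (ch[i] == ")") {
      if (!length(stk)) abort("unbalanced dot-bracket")
      j <- stk[length(stk)]
      stk <- stk[-length(stk)]
      pairs[j] <- i
      pairs[i] <- j
    }
  }
  if (length(stk)) abort("unbalanced dot-bracket")
  ok <- c("A:U", "U:A", "C:G", "G:C", "G:U", "U:G")
  bs <- strsplit(seq, "")[[1]]
  pi <- which(!is.na(pairs))
  bad <- !paste(bs[pi], bs[pairs[pi]], sep = ":") %in% ok
  if (any(bad)) abort("dot-bracket pairs a non-complementary base pair")
  structure(list(id = id, seq = seq, n = n, pairs = pairs,
                 n_pairs = sum(!is.na(pairs)) / 2L,
                 dot_bracket = dot_bracket),
            class = "hairpin_fold")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat("<hairpin_fold> ", x$id, ": ", x$n, " nt, ", x$n_pairs, " pairs\n",
      sep = "")
  cat(x$seq, "\n", x$dot_bracket, "\n", sep = "")
  invisible(x)
}

#' Locate the miR* interval from the folded duplex
#'
#' The miR* is the contiguous interval spanning the pairing partners of the
#' miR positions, trimmed of stray long-range partners (pair-maximization
#' structures can contain a few pairs outside the duplex helix) and shifted
#' to give the canonical 2-nt 3' overhang on each duplex strand.  At least
#' half of the miR positions must be paired, otherwise a "no duplex" error
#' is raised (e.g. a miR placed in the loop).
#'
#' @param fold A `hairpin_fold`.
#' @param mir_start 0-based start of the miR on the precursor.
#' @param mir_len miR length in nt.
#' @return A list with 0-based half-open `start`, `end`, and `arm`
#'   (`"5p"`/`"3p"`) of the miR* interval.
#' @export
locate_star <- function(fold, mir_start, mir_len) {
  stopifnot(inherits(fold, "hairpin_fold"))
  pos <- (mir_start + 1L):(mir_start + mir_len)     # 1-based
  if (pos[1] < 1L || pos[length(pos)] > fold$n) abort("miR interval outside precursor")
  partners <- fold$pairs[pos]
  if (mean(!is.na(partners)) < 0.5) abort("no duplex: fewer than 50% of miR positions are paired")
  partners <- partners[!is.na(partners)]
  # trim partners far from the bulk of the duplex helix
  med <- stats::median(partners)
  partners <- partners[abs(partners - med) <= mir_len]
  mir_is_5p <- med > stats::median(pos)
  shift <- if (mir_is_5p) 2L else -2L
  lo <- min(partners) + shift
  hi <- max(partners) + shift
  lo <- max(lo, 1L)
  hi <- min(hi, fold$n)
  list(start = lo - 1L, end = hi, arm = if (mir_is_5p) "3p" else "5p")
}

# overlap of reads (start0, len) with a window [w0, w1) as a fraction of
# read length; windows may be NULL (no overlap)
read_window_overlap <- function(start, len, window) {
  if (is.null(window)) return(rep(0, length(start)))
  ov <- pmin(start + len, window$end) - pmax(start, window$start)
  pmax(ov, 0) / len
}

#' Apply the five expression criteria to a hairpin read profile
#'
#' The criteria are: (1) at least one miR* read; (2) at least 20 reads on
#' miR and miR* in total; (3) at least 13 miR positions paired to miR*
#' positions in the duplex; (4) the top-3 isomiRs carry at least 85% of the
#' miR-arm reads; (5) the duplex-to-background read ratio exceeds 1 (with
#' zero background reported as `Inf`, passing).  A read is assigned to a
#' window when it overlaps it by at least `min_overlap` of its length; an
#' isomiR is a unique `(start, length)` pair on the miR arm.
#'
#' @param profile Tibble with columns `start` (0-based on the precursor),
#'   `length`, `count` for one hairpin.
#' @param fold A `hairpin_fold` of the precursor.
#' @param mir Optional 0-based half-open miR interval
#'   `list(start =, end =)`; defaults to the highest-count read.
#' @param min_star_reads,min_total_reads,min_duplex_pairs,min_top3_frac
#'   Criterion thresholds (defaults 1, 20, 13, 0.85).
#' @param min_overlap Read-to-window assignment rule (fraction of read
#'   length, default 0.5).
#' @return An object of class `mirna_validation`: criteria `c1..c5`,
#'   the underlying metrics, and `verdict` (all five hold).
#' @export
validate_mirna <- function(profile, fold, mir = NULL,
                           min_star_reads = 1, min_total_reads = 20,
                           min_duplex_pairs = 13, min_top3_frac = 0.85,
                           min_overlap = 0.5) {
  stopifnot(inherits(fold, "hairpin_fold"))
  if (nrow(profile) == 0) abort("empty read profile")
  if (any(profile$count < 1)) abort("read counts must be positive")
  if (any(profile$start < 0 | profile$start + profile$length > fold$n)) {
    abort("reads outside precursor bounds")
  }
  if (is.null(mir)) {
    dom <- profile %>%
      arrange(desc(.data$count), .data$start, .data$length) %>%
      slice(1)
    mir <- list(start = dom$start, end = dom$start + dom$length)
  }
  star <- tryCatch(locate_star(fold, mir$start, mir$end - mir$start),
                   error = function(e) NULL)

  ov_mir <- read_window_overlap(profile$start, profile$length, mir)
  ov_star <- read_window_overlap(profile$start, profile$length, star)
  in_mir <- ov_mir >= min_overlap & ov_mir >= ov_star
  in_star <- ov_star >= min_overlap & !in_mir
  in_bg <- !in_mir & !in_star

  star_count <- sum(profile$count[in_star])
  duplex_count <- sum(profile$count[in_mir | in_star])
  bg_count <- sum(profile$count[in_bg])

  # duplex pairing: miR positions whose partner lies in the miR* window
  mir_pos <- (mir$start + 1L):mir$end
  partners <- fold$pairs[mir_pos]
  duplex_pairs <- if (is.null(star)) 0L else {
    sum(!is.na(partners) & partners > star$start & partners <= star$end)
  }

  iso <- profile[in_mir, , drop = FALSE] %>%
    group_by(.data$start, .data$length) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    arrange(desc(.data$count), .data$start, .data$length)
  mir_total <- sum(iso$count)
  top3 <- if (mir_total == 0) 0 else sum(utils::head(iso$count, 3)) / mir_total

  ratio <- if (bg_count == 0) Inf else duplex_count / bg_count

  crit <- c(c1 = star_count >= min_star_reads,
            c2 = duplex_count >= min_total_reads,
            c3 = duplex_pairs >= min_duplex_pairs,
            c4 = top3 >= min_top3_frac,
            c5 = ratio > 1)
  structure(list(hairpin_id = fold$id,
                 criteria = crit,
                 metrics = list(star_reads = star_count,
                                duplex_reads = duplex_count,
                                duplex_pairs = duplex_pairs,
                                top3_fraction = top3,
                                background_reads = bg_count,
                                background_ratio = ratio),
                 mir = mir, star = star,
                 verdict = all(crit)),
            class = "mirna_validation")
}

#' @export
print.mirna_validation <- function(x, ...) {
  cat("<mirna_validation> ", x$hairpin_id, ": ",
      if (x$verdict) "PASS" else "FAIL", "\n", sep = "")
  cat("  criteria:", paste(names(x$criteria),
                           ifelse(x$criteria, "T", "F"), collapse = " "), "\n")
  invisible(x)
}

#' Validate many hairpins at once
#'
#' Folds each precursor, applies [validate_mirna()] to its read profile and
#' returns one row per hairpin.
#'
#' @param profiles Tibble with columns `hairpin_id`, `start`, `length`,
#'   `count`.
#' @param hairpins Tibble with columns `id`, `seq` (precursors).
#' @param mir_annotations Optional tibble `hairpin_id`, `mir_start`,
#'   `mir_end` (0-based half-open); hairpins absent from it fall back to the
#'   dominant read.
#' @param dot_brackets Optional tibble `hairpin_id`, `dot_bracket` of
#'   externally supplied structures.
#' @param ... Passed on to [validate_mirna()].
#' @return A tibble with per-criterion columns, metrics and `verdict`.
#' @export
validate_profiles <- function(profiles, hairpins, mir_annotations = NULL,
                              dot_brackets = NULL, ...) {
  ids <- unique(profiles$hairpin_id)
  missing <- setdiff(ids, hairpins$id)
  if (length(missing)) abort(paste0("no precursor sequence for ", missing[1]))
  purrr::map_dfr(ids, function(h) {
    seqh <- hairpins$seq[hairpins$id == h]
    fold <- if (!is.null(dot_brackets) && h %in% dot_brackets$hairpin_id) {
      fold_from_dotbracket(seqh, dot_brackets$dot_bracket[dot_brackets$hairpin_id == h], id = h)
    } else {
      fold_hairpin(seqh, id = h)
    }
    mir <- NULL
    if (!is.null(mir_annotations) && h %in% mir_annotations$hairpin_id) {
      a <- mir_annotations[mir_annotations$hairpin_id == h, ]
      mir <- list(start = a$mir_start[1], end = a$mir_end[1])
    }
    rep <- validate_mirna(profiles[profiles$hairpin_id == h, ], fold, mir = mir, ...)
    glance(rep)
  })
}

#' @export
tidy.mirna_validation <- function(x, ...) {
  tibble(hairpin_id = x$hairpin_id,
         criterion = names(x$criteria),
         passed = unname(x$criteria))
}

#' @export
glance.mirna_validation <- function(x, ...) {
  tibble(hairpin_id = x$hairpin_id,
         c1 = x$criteria[["c1"]], c2 = x$criteria[["c2"]],
         c3 = x$criteria[["c3"]], c4 = x$criteria[["c4"]],
         c5 = x$criteria[["c5"]],
         star_reads = x$metrics$star_reads,
         duplex_reads = x$metrics$duplex_reads,
         duplex_pairs = x$metrics$duplex_pairs,
         top3_fraction = x$metrics$top3_fraction,
         background_ratio = x$metrics$background_ratio,
         verdict = x$verdict)
}
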