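# Repression analysis in control vs overexpression transcriptomes:
# per-gene log2 fold changes, the two-sample Kolmogorov-Smirnov comparison
# of targets against the background, the fold-change cutoff for
# down-regulated calls, and the ninth-nucleotide composition test.

#' Per-gene log2 fold changes between two conditions
#'
#' Replicate columns are averaged within each condition first; genes with a
#' zero mean in either condition (non-expressed) are excluded and listed in
#' the `excluded` attribute.
#'
#' @param control,treatment Expression tibbles (first column `gene`, one
#'   column per replicate) over the same gene universe.
#' @return A tibble `gene`, `control_mean`, `treatment_mean`, `lfc`
#'   (log2(treatment/control)), with attribute `excluded` (genes removed
#'   for zero expression).
#' @export
log2_fold_changes <- function(control, treatment) {
  shared <- intersect(control$gene, treatment$gene)
  if (!length(shared)) abort("control and treatment share no genes")
  cm <- rowMeans(as.matrix(control[match(shared, control$gene), -1, drop = FALSE]))
  tm <- rowMeans(as.matrix(treatment[match(shared, treatment$gene), -1, drop = FALSE]))
  zero <- cm == 0 | tm == 0
  out <- tibble(gene = shared[!zero],
                control_mean = cm[!zero],
                treatment_mean = tm[!zero],
                lfc = log2(tm[!zero] / cm[!zero]))
  attr(out, "excluded") <- shared[zero]
  out
}

# asymptotic Kolmogorov survival function Q(lambda) = 2 sum (-1)^(k-1) exp(-2 k^2 lambda^2)
kolmogorov_q <- function(lambda) {
  if (lambda < 1e-3) return(1)
  k <- 1:100
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  min(max(p, 0), 1)
}

ks_statistic <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  pooled <- c(x, y)
  o <- order(pooled)
  steps <- cumsum(ifelse(o <= nx, 1 / nx, -1 / ny))
  vals <- pooled[o]
  keep <- c(diff(vals) != 0, TRUE)   # evaluate ECDF difference after ties
  max(abs(steps[keep]))
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the sup-distance between the two empirical CDFs; the p-value
#' comes from the asymptotic Kolmogorov distribution with effective sample
#' size `n_x n_y / (n_x + n_y)`, or from permutation of the group labels
#' (full enumeration when feasible) for small samples.  Two-sided
#' throughout; the direction of a shift is read off the sign of the median
#' difference separately.
#'
#' @param x,y Numeric samples (e.g. target and non-target log2 fold
#'   changes).
#' @param method `"auto"` (permutation when `min(n) < 10`),
#'   `"asymptotic"`, or `"permutation"`.
#' @param n_perm Monte-Carlo permutations when full enumeration exceeds
#'   `max_enum` label assignments.
#' @param max_enum Largest number of assignments enumerated exactly.
#' @return An object of class `ks_repression` with `statistic`, `p.value`,
#'   `n_x`, `n_y`, `method` (and the samples, for plotting).
#' @export
ks_two_sample <- function(x, y, method = c("auto", "asymptotic", "permutation"),
                          n_perm = 2000, max_enum = 50000) {
  method <- match.arg(method)
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  if (method == "auto") method <- if (min(nx, ny) < 10) "permutation" else "asymptotic"
  d <- ks_statistic(x, y)
  if (method == "asymptotic") {
    ne <- nx * ny / (nx + ny)
    p <- kolmogorov_q(sqrt(ne) * d)
  } else {
    pool <- c(x, y)
    n_comb <- choose(nx + ny, nx)
    eps <- 1e-12
    if (n_comb <= max_enum) {
      idx <- utils::combn(nx + ny, nx)
      ds <- apply(idx, 2, function(i) ks_statistic(pool[i], pool[-i]))
      p <- mean(ds >= d - eps)
    } else {
      ds <- replicate(n_perm, {
        i <- sample.int(nx + ny, nx)
        ks_statistic(pool[i], pool[-i])
      })
      p <- (sum(ds >= d - eps) + 1) / (n_perm + 1)
    }
  }
  structure(list(statistic = d, p.value = p, n_x = nx, n_y = ny,
                 method = method, x = x, y = y),
            class = "ks_repression")
}

#' @export
print.ks_repression <- function(x, ...) {
  cat("<ks_repression> D =", signif(x$statistic, 4),
      " p =", signif(x$p.value, 4),
      " (n =", x$n_x, "vs", x$n_y, ",", x$method, ")\n")
  invisible(x)
}

#' @export
tidy.ks_repression <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p.value,
         n_x = x$n_x, n_y = x$n_y, method = x$method)
}

#' @export
glance.ks_repression <- function(x, ...) tidy(x)

#' Call down-regulated genes at a fold cutoff
#'
#' A gene is called when its treatment/control fold change is at least
#' `fold_cutoff`-fold down, i.e. `lfc <= -log2(fold_cutoff)`.
#'
#' @param lfc_tbl Result of [log2_fold_changes()] (needs `gene`, `lfc`).
#' @param fold_cutoff Repression cutoff, must exceed 1 (default 1.2).
#' @return Character vector of down-regulated genes.
#' @export
call_downregulated <- function(lfc_tbl, fold_cutoff = 1.2) {
  if (fold_cutoff <= 1) abort("fold_cutoff must be > 1")
  lfc_tbl$gene[lfc_tbl$lfc <= -log2(fold_cutoff)]
}

#' Shared down-regulated targets across species
#'
#' Delegates to [pairwise_overlap()] (two species) or [multi_overlap()]
#' (three or more).
#'
#' @param sets Named list of down-regulated gene vectors, one per species.
#' @param map Ortholog map tibble.
#' @return An overlap tibble row.
#' @export
shared_downregulated <- function(sets, map) {
  stopifnot(length(sets) >= 2)
  if (length(sets) == 2) {
    pairwise_overlap(sets[[1]], sets[[2]], map, names(sets),
                     scope = "downregulated")
  } else {
    multi_overlap(sets, map, scope = "downregulated")
  }
}

#' Fisher's exact test on a 2x2 table
#'
#' Two-sided exact test: the p-value sums the hypergeometric probabilities
#' of all tables with the observed margins that are no more probable than
#' the observed one.  The odds ratio is the sample odds ratio
#' `(ad)/(bc)` (`Inf` allowed).
#'
#' @param table 2x2 matrix of non-negative integers with positive margins.
#' @return An object of class `fisher2x2` with `table`, `odds_ratio`,
#'   `p.value`.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) abort("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) abort("table entries must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) abort("zero margin in 2x2 table")
  ft <- fisher.test(table)
  or <- (table[1, 1] * table[2, 2]) / (table[1, 2] * table[2, 1])
  structure(list(table = table, odds_ratio = or, p.value = ft$p.value),
            class = "fisher2x2")
}

#' @export
print.fisher2x2 <- function(x, ...) {
  cat("<fisher2x2> OR =", signif(x$odds_ratio, 4),
      " p =", signif(x$p.value, 4), "\n")
  invisible(x)
}

#' @export
tidy.fisher2x2 <- function(x, ...) {
  tibble(odds_ratio = x$odds_ratio, p.value = x$p.value)
}

#' Base composition opposite mature position 9 at target sites
#'
#' For each 8mer/7mer-m8 site the UTR base pairing mature nucleotide 9 is
#' the position immediately adjacent to the m8-matching end of the site
#' (site start - 1 in 0-based UTR coordinates; start - 2 for 7mer-1A
#' sites, whose match begins at the mature-7 register).  Sites lacking
#' that context position (at the UTR boundary) are excluded and counted.
#'
#' @param sites Tibble with columns `gene`, `utr_position`, `site_class`.
#' @param utrs Tibble with columns `gene`, `seq`.
#' @return A tibble `base` (A/C/G/U), `n`, with attribute `excluded`
#'   (number of boundary sites dropped).
#' @export
position9_composition <- function(sites, utrs) {
  stopifnot(all(c("gene", "utr_position", "site_class") %in% names(sites)))
  offset <- ifelse(sites$site_class == "7mer-1A", 2L, 1L)
  ctx1 <- sites$utr_position + 1L - offset     # 1-based context position
  seqs <- utrs$seq[match(sites$gene, utrs$gene)]
  if (anyNA(seqs)) abort("site gene missing from UTR table")
  keep <- ctx1 >= 1
  base <- substring(seqs[keep], ctx1[keep], ctx1[keep])
  counts <- table(factor(base, levels = c("A", "C", "G", "U")))
  out <- tibble(base = names(counts), n = as.integer(counts))
  attr(out, "excluded") <- sum(!keep)
  out
}

#' Compare a base's enrichment at position 9 between two species
#'
#' Builds the 2x2 table (species x base-of-interest vs rest) from two
#' [position9_composition()] count tables and applies [fisher_exact()].
#'
#' @param counts_a,counts_b Count tibbles from [position9_composition()].
#' @param base The base of interest (e.g. `"A"` or `"C"`).
#' @return A `fisher2x2` object.
#' @export
compare_position9 <- function(counts_a, counts_b, base) {
  pick <- function(ct) c(sum(ct$n[ct$base == base]), sum(ct$n[ct$base != base]))
  tab <- rbind(pick(counts_a), pick(counts_b))
  dimnames(tab) <- list(species = c("a", "b"), base = c(base, "other"))
  fisher_exact(tab)
}
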