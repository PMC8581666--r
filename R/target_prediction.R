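# Canonical seed-match target prediction on expressed 3'UTRs: TPM
# normalization, the expression filter, site scanning (8mer / 7mer-m8 /
# 7mer-1A) and per-member plus pooled target sets.

#' TPM-normalize a count table
#'
#' `TPM_g = (count_g / length_kb_g) / sum_h(count_h / length_kb_h) * 1e6`
#' per sample; every sample column sums to 1e6.
#'
#' @param counts Expression tibble (first column `gene`, one column per
#'   sample) in count units.
#' @param lengths Tibble with columns `gene`, `length` (nt), or a named
#'   numeric vector of nt lengths.
#' @return A tibble of the same shape in TPM units (attribute
#'   `unit = "TPM"`).
#' @export
compute_tpm <- function(counts, lengths) {
  if (is.data.frame(lengths)) lengths <- setNames(lengths$length, lengths$gene)
  g <- counts$gene
  if (!all(g %in% names(lengths))) abort("missing gene lengths")
  len_kb <- lengths[g] / 1000
  if (any(len_kb <= 0)) abort("gene lengths must be positive")
  out <- counts
  for (s in names(counts)[-1]) {
    rate <- unname(counts[[s]] / len_kb)
    tot <- sum(rate)
    if (tot == 0) abort(paste0("sample ", s, " has zero total expression"))
    out[[s]] <- rate / tot * 1e6
  }
  attr(out, "unit") <- "TPM"
  out
}

#' Keep genes passing the mean-expression filter
#'
#' Genes whose across-sample mean is below the threshold are removed (the
#' boundary value itself is kept).
#'
#' @param tpm Expression tibble in TPM units.
#' @param threshold Minimum mean TPM (default 1).
#' @return Character vector of retained gene ids.
#' @export
filter_expressed <- function(tpm, threshold = 1) {
  vals <- as.matrix(tpm[, -1])
  tpm$gene[rowMeans(vals) >= threshold]
}

#' Find canonical seed-match sites in a 3'UTR
#'
#' Scans the UTR sense strand for matches to the reverse complement of the
#' seed (mature positions 2-8).  Site classes: `8mer` = full 7-nt match
#' followed by A (opposite mature position 1); `7mer-m8` = full 7-nt match
#' without the A; `7mer-1A` = match to mature 2-7 followed by A.  Each
#' site is reported once under its most specific class
#' (8mer > 7mer-m8 > 7mer-1A); overlapping sites are all reported.
#'
#' @param utr UTR sequence (RNA or DNA; normalized to RNA).
#' @param seed 7-nt seed (no ambiguous bases).
#' @param site_classes Classes to report; default `c("8mer", "7mer-m8")`,
#'   add `"7mer-1A"` for the weakest canonical class.
#' @param collapse When `TRUE` (default) each position is reported once
#'   under its most specific class; when `FALSE` every class a position
#'   satisfies is reported (an 8mer position also appears as 7mer-m8 and
#'   7mer-1A).
#' @return A tibble with `utr_position` (0-based start of the matched
#'   k-mer) and `site_class`.
#' @export
find_sites <- function(utr, seed, site_classes = c("8mer", "7mer-m8"),
                       collapse = TRUE) {
  utr <- normalize_rna(utr)
  if (nchar(seed) != 7) abort("seed must be exactly 7 nt")
  seed <- normalize_rna(seed)
  if (grepl("N", seed, fixed = TRUE)) abort("ambiguous base in seed")
  bad <- setdiff(site_classes, c("8mer", "7mer-m8", "7mer-1A"))
  if (length(bad)) abort(paste0("unknown site class: ", bad[1]))
  m <- rna_revcomp(seed)            # pairs mature 8..2
  m6 <- substr(m, 2, 7)             # pairs mature 7..2
  L <- nchar(utr)
  out <- tibble(utr_position = integer(), site_class = character())
  if (L >= 7) {
    s7 <- seq_len(L - 6)
    hits7 <- s7[substring(utr, s7, s7 + 6) == m]
    if (length(hits7)) {
      nxt <- substring(utr, hits7 + 7, hits7 + 7)
      is8 <- nxt == "A"
      if (collapse) {
        out <- bind_rows(out, tibble(utr_position = hits7 - 1L,
                                     site_class = ifelse(is8, "8mer", "7mer-m8")))
      } else {
        out <- bind_rows(out,
                         tibble(utr_position = hits7[is8] - 1L, site_class = "8mer"),
                         tibble(utr_position = hits7 - 1L, site_class = "7mer-m8"))
      }
    }
    s6 <- seq_len(L - 6)            # 6-mer + A needs 7 positions
    hit6 <- s6[substring(utr, s6, s6 + 5) == m6 &
                 substring(utr, s6 + 6, s6 + 6) == "A"]
    if (length(hit6)) {
      if (collapse) {
        # part of an 8mer (already reported) when preceded by the m8 base
        prev <- ifelse(hit6 > 1, substring(utr, hit6 - 1, hit6 - 1), "")
        hit6 <- hit6[prev != substr(m, 1, 1)]
      }
      if (length(hit6)) {
        out <- bind_rows(out, tibble(utr_position = hit6 - 1L,
                                     site_class = "7mer-1A"))
      }
    }
  }
  out %>%
    filter(.data$site_class %in% site_classes) %>%
    arrange(.data$utr_position)
}

#' Scan member seeds against a species' expressed UTRs
#'
#' @param utrs Tibble with columns `gene`, `seq` (one species' 3'UTRs).
#' @param seeds Tibble with columns `member`, `seed`.
#' @param expressed Optional character vector of expressed genes; genes
#'   outside it are excluded before scanning.
#' @param site_classes Passed to [find_sites()].
#' @return A tibble of sites: `member`, `gene`, `utr_position`,
#'   `site_class`.
#' @export
scan_targets <- function(utrs, seeds, expressed = NULL,
                         site_classes = c("8mer", "7mer-m8")) {
  stopifnot(all(c("gene", "seq") %in% names(utrs)),
            all(c("member", "seed") %in% names(seeds)))
  if (!is.null(expressed)) utrs <- filter(utrs, .data$gene %in% expressed)
  purrr::map_dfr(seq_len(nrow(seeds)), function(i) {
    purrr::map_dfr(seq_len(nrow(utrs)), function(j) {
      hits <- find_sites(utrs$seq[j], seeds$seed[i], site_classes)
      if (nrow(hits) == 0) return(NULL)
      mutate(hits, member = seeds$member[i], gene = utrs$gene[j],
             .before = 1)
    })
  })
}

#' Predict per-member and pooled cluster target sets
#'
#' Restricts the UTR universe to expressed genes, scans every member seed
#' and returns the genes with at least one qualifying site, per member and
#' pooled over the cluster (`member = "pooled"`, the union).
#'
#' @inheritParams scan_targets
#' @return A tibble with columns `member`, `gene`, `n_sites` (with
#'   `n_sites = NA` on pooled rows); the per-site table is attached as
#'   attribute `sites`.
#' @export
predict_targets <- function(utrs, seeds, expressed = NULL,
                            site_classes = c("8mer", "7mer-m8")) {
  sites <- scan_targets(utrs, seeds, expressed, site_classes)
  if (nrow(sites) == 0) {
    out <- tibble(member = character(), gene = character(), n_sites = integer())
    attr(out, "sites") <- sites
    return(out)
  }
  per_member <- sites %>%
    group_by(.data$member, .data$gene) %>%
    summarise(n_sites = n(), .groups = "drop")
  pooled <- per_member %>%
    distinct(.data$gene) %>%
    mutate(member = "pooled", n_sites = NA_integer_) %>%
    select("member", "gene", "n_sites")
  out <- bind_rows(per_member, pooled)
  attr(out, "sites") <- sites
  out
}
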