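# Readers and writers for the plain-text formats the pipeline touches:
# FASTA (sequences), newick (species trees), TSV (read profiles, expression
# tables, presence matrices, ortholog maps).  Sequences are normalized to the
# RNA alphabet internally; DNA input is accepted and converted.

IUPAC_NT <- c("A", "C", "G", "U", "T", "N")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases the sequence and replaces T with U.  The operation is
#' idempotent.  Characters outside `A C G U T N` raise an error.
#'
#' @param seq Character vector of nucleotide strings.
#' @param id Optional ids used in error messages.
#' @return Character vector over `{A,C,G,U,N}`.
#' @export
normalize_rna <- function(seq, id = NULL) {
  out <- chartr("tT", "uU", seq)
  out <- toupper(out)
  bad <- stringr::str_detect(out, "[^ACGUN]")
  if (any(bad)) {
    lab <- if (is.null(id)) which(bad)[1] else id[bad][1]
    abort(paste0("non-IUPAC nucleotide character in sequence '", lab, "'"))
  }
  out
}

#' Reverse complement of an RNA string
#'
#' @param seq Character vector of RNA strings (A/C/G/U/N).
#' @return Reverse-complemented character vector.
#' @export
rna_revcomp <- function(seq) {
  comp <- chartr("ACGUN", "UGCAN", seq)
  vapply(strsplit(comp, ""), function(x) paste(rev(x), collapse = ""), "")
}

#' Read a FASTA file into a tibble of sequence records
#'
#' One row per record with columns `id`, `seq` and `description`.  With
#' `alphabet = "rna"` (the default and the package's internal convention)
#' sequences are normalized to RNA (T becomes U).  Duplicate ids, empty
#' sequences and non-IUPAC characters are hard errors.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"rna"` (normalize T to U) or `"asis"`.
#' @return A tibble with columns `id`, `seq`, `description`.
#' @export
read_fasta <- function(path, alphabet = c("rna", "asis")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  headers <- names(set)
  id <- stringr::str_extract(headers, "^\\S+")
  description <- stringr::str_trim(stringr::str_remove(headers, "^\\S+\\s*"))
  if (anyNA(id) || any(id == "")) abort("FASTA record with empty id")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate FASTA id: ", id[duplicated(id)][1]))
  }
  seq <- as.character(set)
  if (any(nchar(seq) == 0)) {
    abort(paste0("empty sequence for FASTA record '", id[nchar(seq) == 0][1], "'"))
  }
  if (alphabet == "rna") {
    seq <- normalize_rna(seq, id)
  } else {
    bad <- stringr::str_detect(toupper(seq), "[^ACGUTN]")
    if (any(bad)) abort(paste0("non-IUPAC character in record '", id[bad][1], "'"))
  }
  tibble(id = id, seq = unname(seq), description = description)
}

#' Write sequence records to FASTA
#'
#' @param records Tibble with columns `id`, `seq` and optionally
#'   `description`.
#' @param path Output path.
#' @param alphabet `"asis"` (default: write sequences exactly as stored) or
#'   `"dna"` (U back-transcribed to T).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, alphabet = c("asis", "dna")) {
  alphabet <- match.arg(alphabet)
  stopifnot(all(c("id", "seq") %in% names(records)))
  seq <- records$seq
  if (alphabet == "dna") seq <- chartr("uU", "tT", seq)
  desc <- if ("description" %in% names(records)) records$description else ""
  hdr <- ifelse(is.na(desc) | desc == "", records$id, paste(records$id, desc))
  set <- Biostrings::BStringSet(setNames(seq, hdr))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a rooted species tree from a newick file or string
#'
#' Thin wrapper over [ape::read.tree()] adding the checks the pipeline
#' relies on: at least two uniquely-labelled leaves and a rooted topology.
#'
#' @param path Path to a newick file, or a newick string (detected by a
#'   terminal `;`).
#' @return An object of class `phylo`.
#' @export
read_newick <- function(path) {
  as_text <- grepl("[()]", path) || grepl(";\\s*$", path)
  tree <- tryCatch(
    if (as_text) ape::read.tree(text = path) else ape::read.tree(path),
    error = function(e) abort(paste0("could not parse newick input: ", conditionMessage(e))),
    warning = function(w) abort(paste0("could not parse newick input: ", conditionMessage(w))))
  if (is.null(tree)) abort("could not parse newick input")
  if (ape::Ntip(tree) < 2) abort("species tree needs at least 2 leaves")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate leaf label: ", tree$tip.label[duplicated(tree$tip.label)][1]))
  }
  if (!ape::is.rooted(tree)) abort("species tree must be rooted")
  tree
}

#' Read an expression table (genes x samples) from TSV
#'
#' First column holds gene ids, remaining columns one sample each.  Lines
#' starting with `#` are ignored.  Negative values and duplicate gene ids
#' are hard errors.
#'
#' @param path Path to a TSV file.
#' @param unit One of `"counts"`, `"TPM"`, `"FPKM"`; recorded as the
#'   attribute `unit` on the returned tibble.
#' @return A tibble whose first column is `gene`, with one numeric column
#'   per sample.
#' @export
read_expression_table <- function(path, unit = c("counts", "TPM", "FPKM")) {
  unit <- match.arg(unit)
  tbl <- suppressWarnings(readr::read_tsv(path, comment = "#",
                                          show_col_types = FALSE,
                                          progress = FALSE))
  if (nrow(readr::problems(tbl)) > 0) abort("ragged rows in expression table")
  if (nrow(tbl) == 0 || ncol(tbl) < 2) abort("expression table needs >= 1 gene and >= 1 sample")
  names(tbl)[1] <- "gene"
  tbl$gene <- as.character(tbl$gene)
  if (anyDuplicated(tbl$gene)) abort("duplicate gene ids in expression table")
  vals <- as.matrix(tbl[, -1])
  if (!is.numeric(vals)) abort("non-numeric expression values")
  if (anyNA(vals)) abort("missing (ragged or NA) expression values")
  if (any(vals < 0)) abort("negative expression values")
  attr(tbl, "unit") <- unit
  tbl
}

#' Read per-hairpin small-RNA read profiles from TSV
#'
#' Expected columns: `hairpin_id`, `start` (0-based offset on the
#' precursor), `length` (nt) and `count`.
#'
#' @param path Path to a TSV file.
#' @return A tibble with those four columns.
#' @export
read_read_profiles <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  need <- c("hairpin_id", "start", "length", "count")
  if (!all(need %in% names(tbl))) {
    abort(paste0("read-profile TSV must have columns: ", paste(need, collapse = ", ")))
  }
  if (any(tbl$count < 1)) abort("read counts must be positive")
  tbl[need]
}

#' Read a member x species presence matrix from TSV
#'
#' Wide TSV with a `member` column and one 0/1 column per species; returned
#' in long (tidy) form.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `member`, `species`, `present` (logical).
#' @export
read_presence_matrix <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  names(tbl)[1] <- "member"
  long <- tidyr::pivot_longer(tbl, -"member", names_to = "species",
                              values_to = "present")
  mutate(long, present = as.logical(.data$present))
}

#' Read a one-to-one ortholog map from TSV
#'
#' One column per species; each row is one ortholog tuple.  `NA` or empty
#' cells mean the tuple lacks a member in that species.  A gene appearing
#' in two tuples of the same species is a hard error.
#'
#' @param path Path to a TSV file.
#' @return A tibble with a `tuple` id column plus one column per species.
#' @export
read_ortholog_map <- function(path) {
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  for (sp in names(tbl)) {
    v <- tbl[[sp]][!is.na(tbl[[sp]]) & tbl[[sp]] != ""]
    if (anyDuplicated(v)) abort(paste0("gene in two ortholog tuples for species ", sp))
  }
  mutate(tbl, tuple = paste0("og", seq_len(nrow(tbl))), .before = 1)
}

#' Write a tibble as TSV with a provenance comment line
#'
#' @param x A data frame.
#' @param path Output path.
#' @param stage Name of the producing stage, written on a leading `#` line.
#' @return `path`, invisibly.
#' @export
write_stage_tsv <- function(x, path, stage = "mircluster") {
  writeLines(paste0("# produced by mircluster::", stage), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  invisible(path)
}
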